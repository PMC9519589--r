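#' Configuration of the synthetic colony simulator
#'
#' Parameterizes a stochastic branching simulation of clonal colony growth at
#' the tracking-output level (no pixels): generation-dependent bipotent
#' division outcomes, state-dependent lognormal cycle times and death,
#' committed-lineage propagation and Mk endomitosis, isotropic random-walk
#' motility with state-dependent step scale, lineage-marker onset delays and
#' the non-uniform acquisition schedule (a single frame in the unimaged first
#' 24 h, 2-h frames to 60 h, 10-min frames after).
#'
#' Defaults encode the control-condition study system: mean cycle times of
#' 15.8 h (bipotent MEP), 15.5 h (E-destined), 25.5 h (Mk-destined), 10.2 h
#' (committed ErP) and 35.7 h (committed MkP); 15.7% of plated cells dying
#' before progeny; a 2:1 E:Mk commitment bias (`pi_E = 2/3`); Mk-destined
#' symmetric self-renewal for on average 2.5 (at most 5) committed
#' generations before endomitosis; E-destined death below 5% appearing from
#' generation 6; and motility ordered MkP > bipotent > ErP.
#'
#' @param seed integer seed (mandatory).
#' @param n_roots number of plated cells.
#' @param root_type `"MEP"`, `"MkP"` or `"ErP"`.
#' @param condition `"control"`, `"noTPO"` or `"noEPO"`; non-control
#'   conditions are derived with [condition_variant()].
#' @param G_max maximum tracked generation (default 13); bipotent cells
#'   beyond it are censored at movie end.
#' @param movie_hours acquisition length (default 168 = 7 days).
#' @param outcome_model a `mep_markov` parameter object; default built from
#'   `pi_E` and `exhaustion_shift` by [default_outcome_model()].
#' @param pi_E probability that a committed daughter is E-destined.
#' @param exhaustion_mode `"independent_draws"` (each exhaustion daughter's
#'   lineage drawn independently with `pi_E`; allows E-only/Mk-only colonies
#'   from true bipotent roots) or `"mixed_pair"` (always one E + one Mk).
#' @param cycle_mean,cycle_cv lognormal cycle-time means (hours) per state
#'   and shared coefficient of variation.
#' @param root_first_division_delay extra hours added to the plated cell's
#'   first cycle (seeding artifact; first division lands in 24-48 h).
#' @param death per-cycle death probabilities per state;
#'   `root_predivision` is the probability a plated cell dies before any
#'   progeny.
#' @param e_death_onset_generation E-destined death applies only from this
#'   generation on.
#' @param mk_mature_probs distribution of committed Mk generations before
#'   endomitosis, over `1:length(mk_mature_probs)`.
#' @param e_commit_max_gen committed E generations after which tracking is
#'   lost to crowding.
#' @param step_scale random-walk step scale per state, micrometres per
#'   sqrt(hour).
#' @param drift per-state directed-motion speed (micrometres per hour),
#'   default 0 (pure isotropic walk). When positive, each cell moves with a
#'   persistent random heading in addition to its diffusive steps, giving
#'   directionality values concentrated above 1 as persistently migrating
#'   cells show.
#' @param marker_delay marker onset delays (hours after commitment; after
#'   plating for sorted committed roots).
#' @param cd235a_suppressed suppress CD235a onset (the noEPO phenotype).
#' @param sparse_until,mid_interval,mid_until,late_interval acquisition
#'   schedule knobs (hours).
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(seed,
                             n_roots = 50L,
                             root_type = c("MEP", "MkP", "ErP"),
                             condition = c("control", "noTPO", "noEPO"),
                             G_max = 13L,
                             movie_hours = 168,
                             outcome_model = NULL,
                             pi_E = 2 / 3,
                             exhaustion_mode = c("independent_draws",
                                                 "mixed_pair"),
                             cycle_mean = c(bipotent = 15.8,
                                            E_destined = 15.5,
                                            Mk_destined = 25.5,
                                            ErP = 10.2, MkP = 35.7),
                             cycle_cv = 0.3,
                             root_first_division_delay = 24,
                             death = c(root_predivision = 0.157,
                                       bipotent = 0.01, E_destined = 0.03,
                                       Mk_destined = 0.01,
                                       ErP = 0.02, MkP = 0.02),
                             e_death_onset_generation = 6L,
                             mk_mature_probs = c(0.3, 0.25, 0.2, 0.15, 0.1),
                             e_commit_max_gen = 7L,
                             step_scale = c(bipotent = 7, E_destined = 5,
                                            Mk_destined = 10,
                                            ErP = 3, MkP = 12),
                             drift = c(bipotent = 0, E_destined = 0,
                                       Mk_destined = 0, ErP = 0, MkP = 0),
                             marker_delay = c(CD41 = 24, CD71bright = 24,
                                              CD235a = 96),
                             cd235a_suppressed = FALSE,
                             sparse_until = 24, mid_interval = 2,
                             mid_until = 60, late_interval = 1 / 6) {
  if (missing(seed)) stop("seed is mandatory")
  root_type <- match.arg(root_type)
  condition <- match.arg(condition)
  exhaustion_mode <- match.arg(exhaustion_mode)
  if (is.null(outcome_model)) outcome_model <- default_outcome_model(pi_E)
  stopifnot(inherits(outcome_model, "mep_markov"),
            pi_E >= 0, pi_E <= 1, all(cycle_mean > 0), cycle_cv > 0,
            all(death >= 0), all(death <= 1),
            abs(sum(mk_mature_probs) - 1) < 1e-9,
            movie_hours > 0, G_max >= 1,
            sparse_until < mid_until, mid_until <= movie_hours,
            mid_interval > 0, late_interval > 0)
  structure(list(seed = as.integer(seed), n_roots = as.integer(n_roots),
                 root_type = root_type, condition = condition,
                 G_max = as.integer(G_max), movie_hours = movie_hours,
                 outcome_model = outcome_model, pi_E = pi_E,
                 exhaustion_mode = exhaustion_mode,
                 cycle_mean = cycle_mean, cycle_cv = cycle_cv,
                 root_first_division_delay = root_first_division_delay,
                 death = death,
                 e_death_onset_generation = as.integer(e_death_onset_generation),
                 mk_mature_probs = mk_mature_probs,
                 e_commit_max_gen = as.integer(e_commit_max_gen),
                 step_scale = step_scale, drift = drift,
                 marker_delay = marker_delay,
                 cd235a_suppressed = cd235a_suppressed,
                 sparse_until = sparse_until, mid_interval = mid_interval,
                 mid_until = mid_until, late_interval = late_interval),
            class = "synthetic_config")
}

#' Default generation-dependent outcome model for the simulator
#'
#' A shared (from-state-independent) parameterization in which expansion
#' dominates the first generations, maintenance rises through mid
#' generations with an E:Mk split of `pi_E`, and exhaustion takes over late
#' — the transient-expansion-then-exhaustion profile of bipotent MEPs.
#'
#' @param pi_E E share of maintenance commitment.
#' @param exhaustion_shift additive shift on the exhaustion intercept
#'   (positive = earlier exhaustion; used by [condition_variant()]).
#' @return a `mep_markov` parameter object.
#' @export
default_outcome_model <- function(pi_E = 2 / 3, exhaustion_shift = 0) {
  mep_markov_params(
    alpha = c(maintenance_E = -1.1 + log(pi_E),
              maintenance_Mk = -1.1 + log(1 - pi_E),
              exhaustion = -4 + exhaustion_shift),
    beta = c(maintenance_E = 1.0, maintenance_Mk = 1.0, exhaustion = 2.2),
    shared = TRUE)
}

#' Acquisition frame times
#'
#' The non-uniform schedule: one frame at plating, none until
#' `sparse_until`, frames every `mid_interval` hours to `mid_until`, then
#' every `late_interval` hours to the end of the movie.
#'
#' @param config a [synthetic_config()].
#' @return strictly increasing numeric vector of hours.
#' @export
acquisition_times <- function(config) {
  mid_end <- min(config$mid_until, config$movie_hours)
  times <- c(0, seq(config$sparse_until, mid_end, by = config$mid_interval))
  if (config$movie_hours > mid_end)
    times <- c(times, seq(mid_end + config$late_interval, config$movie_hours,
                          by = config$late_interval))
  unique(times)
}

#' Derive a cytokine-deprivation condition variant of a control config
#'
#' Applies the configured qualitative effects of withdrawing thrombopoietin
#' (`noTPO`) or erythropoietin (`noEPO`): increased death in all states,
#' lengthened cycle times (strongest without TPO), an earlier-exhaustion
#' shift of the outcome model, and (noEPO) suppressed CD235a onset. The
#' commitment bias `pi_E` is left unchanged: these cytokines support
#' survival and self-renewal, not fate choice.
#'
#' @param base_config a control [synthetic_config()].
#' @param condition `"noTPO"` or `"noEPO"`.
#' @return a new `synthetic_config`.
#' @export
condition_variant <- function(base_config, condition) {
  stopifnot(inherits(base_config, "synthetic_config"))
  if (base_config$condition != "control")
    stop("base_config must be a control configuration")
  eff <- switch(condition,
    noTPO = list(death_mult = 2, root_death_mult = 1.5, cycle_mult = 1.25,
                 exhaustion_shift = 0.7, cd235a_suppressed = FALSE),
    noEPO = list(death_mult = 2, root_death_mult = 1.5, cycle_mult = 1.1,
                 exhaustion_shift = 0.7, cd235a_suppressed = TRUE),
    stop("unknown condition: ", condition))
  cfg <- base_config
  cfg$condition <- condition
  d <- cfg$death * eff$death_mult
  d[d > 1] <- 1
  cfg$death <- d
  cfg$death[["root_predivision"]] <-
    min(1, base_config$death[["root_predivision"]] * eff$root_death_mult)
  cfg$cycle_mean <- cfg$cycle_mean * eff$cycle_mult
  cfg$outcome_model <- default_outcome_model(cfg$pi_E, eff$exhaustion_shift)
  cfg$cd235a_suppressed <- eff$cd235a_suppressed
  cfg
}

# lognormal draw with given mean and CV
rlnorm_mean <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one colony
#'
#' Grows a single plated cell into a colony under the configured rules and
#' returns the resulting [lineage_tree()] (with trajectories sampled at the
#' acquisition schedule and endpoint marker calls) together with the
#' per-cell ground truth and the bipotent division event log.
#'
#' Cell records carry the true birth/end times; the emitted trajectory (and
#' hence the track file) is restricted to acquisition frames, as a tracker
#' would see it.
#'
#' @param config a [synthetic_config()].
#' @param root_seed optional seed set before drawing this colony (when
#'   absent the current RNG stream is used, as in [generate_colonies()]).
#' @param id_prefix prefix for cell ids (keeps ids unique across colonies).
#' @return list with elements `tree`, `truth` (data frame) and `events`
#'   (data frame).
#' @export
generate_colony <- function(config, root_seed = NULL, id_prefix = "c1") {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(root_seed)) set.seed(root_seed)
  movie <- config$movie_hours
  sched <- acquisition_times(config)

  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("%s_%04d", id_prefix, counter)
  }

  cells <- list()    # record fields, children filled as we go
  truth <- list()
  events <- list()

  root_state <- switch(config$root_type, MEP = "bipotent",
                       MkP = "MkP", ErP = "ErP")

  # one cell; returns its id. commit_time: marker clock origin for committed
  # lineages; depth: committed-generation counter; mk_depth: maturation depth
  # drawn at the committed-lineage founder.
  grow <- function(parent_id, state, gen, birth, from_state,
                   commit_time = NA_real_, depth = 0L, mk_depth = NA_integer_) {
    id <- new_id()
    is_root <- is.na(parent_id)
    cycle <- rlnorm_mean(1L, config$cycle_mean[[state_group(state)]],
                         config$cycle_cv)
    if (is_root) cycle <- cycle + config$root_first_division_delay
    t_div <- birth + cycle

    p_death <- if (is_root) config$death[["root_predivision"]]
      else if (state == "bipotent") config$death[["bipotent"]]
      else if (state_group(state) %in% c("E_destined", "ErP")) {
        if (gen >= config$e_death_onset_generation || state == "ErP")
          config$death[[state_group(state)]] else 0
      } else config$death[[state_group(state)]]
    dies <- stats::runif(1L) < p_death

    end <- t_div; end_event <- "divided"; kids <- character()
    outcome <- NA_character_
    if (dies) {
      end <- birth + (0.25 + 0.75 * stats::runif(1L)) * cycle
      if (end > movie) { end <- movie; end_event <- "movie_end" }
      else end_event <- "died"
    } else if (t_div > movie) {
      end <- movie; end_event <- "movie_end"
    } else if (state == "bipotent") {
      if (gen > config$G_max) {     # beyond the tracked range: censored
        end <- movie; end_event <- "movie_end"
      } else {
        om <- config$outcome_model
        from <- if (om$shared) "any" else from_state
        p <- mk_probs(om$coefficients, om$layout, from, gen)
        outcome <- sample(om$outcomes, 1L, prob = p)
        events[[length(events) + 1L]] <<- data.frame(
          parent_id = id, from_state = from_state, generation = gen,
          outcome = outcome, division_time = end,
          stringsAsFactors = FALSE)
        kid_states <- switch(outcome,
          expansion = c("bipotent", "bipotent"),
          maintenance_E = c("bipotent", "E_destined"),
          maintenance_Mk = c("bipotent", "Mk_destined"),
          exhaustion = if (config$exhaustion_mode == "mixed_pair")
            c("E_destined", "Mk_destined")
          else ifelse(stats::runif(2L) < config$pi_E,
                      "E_destined", "Mk_destined"))
        kids <- unname(vapply(kid_states, function(ks) {
          grow(id, ks, gen + 1L, end, from_state = outcome,
               commit_time = if (ks == "bipotent") NA_real_ else end,
               depth = if (ks == "bipotent") 0L else 1L,
               mk_depth = if (ks == "Mk_destined")
                 sample(seq_along(config$mk_mature_probs), 1L,
                        prob = config$mk_mature_probs)
               else NA_integer_)
        }, character(1)))
      }
    } else if (state_group(state) %in% c("E_destined", "ErP")) {
      if (depth >= config$e_commit_max_gen) {   # crowding: track lost
        end <- t_div; end_event <- "lost"
        if (end > movie) { end <- movie; end_event <- "movie_end" }
      } else {
        kids <- vapply(1:2, function(i)
          grow(id, state, gen + 1L, end, from_state = from_state,
               commit_time = commit_time, depth = depth + 1L),
          character(1))
      }
    } else {                                     # Mk lineage
      if (depth >= mk_depth) {
        end <- t_div; end_event <- "endomitosis"
        if (end > movie) { end <- movie; end_event <- "movie_end" }
      } else {
        kids <- vapply(1:2, function(i)
          grow(id, state, gen + 1L, end, from_state = from_state,
               commit_time = commit_time, depth = depth + 1L,
               mk_depth = mk_depth),
          character(1))
      }
    }

    markers <- marker_calls(config, state, end, end_event,
                            if (is_root && state != "bipotent") 0
                            else commit_time)
    cells[[id]] <<- list(cell_id = id, parent_id = parent_id,
                         birth_time = birth, end_time = end,
                         end_event = end_event, markers = markers,
                         children = kids, state = state)
    truth[[length(truth) + 1L]] <<- data.frame(
      cell_id = id, parent_id = ifelse(is.na(parent_id), "", parent_id),
      true_state = state, generation = gen,
      birth_time = birth, end_time = end, end_event = end_event,
      outcome = outcome, from_state = from_state,
      step_scale = config$step_scale[[state_group(state)]],
      stringsAsFactors = FALSE)
    id
  }

  # committed Mk roots need a maturation depth too
  root_mk_depth <- if (root_state == "MkP")
    sample(seq_along(config$mk_mature_probs), 1L,
           prob = config$mk_mature_probs) else NA_integer_
  root_id <- grow(NA_character_, root_state, 1L, 0, from_state = "start",
                  commit_time = if (root_state == "bipotent") NA_real_ else 0,
                  depth = if (root_state == "bipotent") 0L else 1L,
                  mk_depth = root_mk_depth)

  truth <- do.call(rbind, truth)
  truth$true_fate_label <- true_fate_labels(cells, truth, root_id,
                                            config$root_type)
  events <- if (length(events)) do.call(rbind, events)
    else data.frame(parent_id = character(), from_state = character(),
                    generation = integer(), outcome = character(),
                    division_time = numeric())

  tree <- build_tree_with_tracks(cells, root_id, config, sched)
  list(tree = tree, truth = truth, events = events)
}

state_group <- function(state) state   # states already name their group

marker_calls <- function(config, state, end, end_event, commit_time) {
  if (state == "bipotent" || is.na(commit_time)) return(character())
  d <- config$marker_delay
  if (state %in% c("E_destined", "ErP")) {
    m <- character()
    if (end >= commit_time + d[["CD71bright"]]) m <- c(m, "CD71bright")
    if (!config$cd235a_suppressed && end >= commit_time + d[["CD235a"]])
      m <- c(m, "CD235a")
    m
  } else {
    if (end >= commit_time + d[["CD41"]]) "CD41" else character()
  }
}

# realized-fate truth labels, computed bottom-up inside the simulator
# (independent of the package's marker-based inference): committed cells get
# their lineage; a bipotent cell is E_- or Mk_destined only if all realized
# descendants are of that single lineage and none remained bipotent.
true_fate_labels <- function(cells, truth, root_id, root_type) {
  state_of <- stats::setNames(truth$true_state, truth$cell_id)
  lab <- stats::setNames(character(nrow(truth)), truth$cell_id)
  content <- list()
  post <- character(0)
  walk <- function(id) {
    for (k in cells[[id]]$children) walk(k)
    post[[length(post) + 1L]] <<- id
  }
  walk(root_id)
  post <- unlist(post)
  for (id in post) {
    st <- state_of[[id]]
    content[[id]] <- if (st %in% c("E_destined", "ErP")) "E"
      else if (st %in% c("Mk_destined", "MkP")) "Mk"
      else {
        kids <- cells[[id]]$children
        if (length(kids) == 0L) "open"      # censored bipotent leaf
        else unique(unlist(content[kids]))
      }
    lab[[id]] <- if (st == "ErP") "committed_ErP"
      else if (st == "MkP") "committed_MkP"
      else if (st != "bipotent") st
      else {
        cc <- content[[id]]
        if (identical(cc, "E")) "E_destined"
        else if (identical(cc, "Mk")) "Mk_destined"
        else "bipotent"
      }
  }
  unname(lab[truth$cell_id])
}

# sample trajectories on the acquisition schedule and assemble the tree
build_tree_with_tracks <- function(cells, root_id, config, sched) {
  pos <- list()   # final position per cell
  order <- character(0)
  walk <- function(id) {
    order[[length(order) + 1L]] <<- id
    for (k in cells[[id]]$children) walk(k)
  }
  walk(root_id)
  order <- unlist(order)

  records <- list()
  truth_state <- NULL
  for (id in order) {
    c <- cells[[id]]
    idx <- which(sched >= c$birth_time - 1e-9 & sched <= c$end_time + 1e-9)
    if (length(idx) == 0L)
      idx <- which(sched > c$birth_time)[1L]   # first frame after birth
    times <- sched[idx]
    start <- if (is.na(c$parent_id)) c(0, 0) else pos[[c$parent_id]]
    st <- state_group_of(cells, id, config)
    scale <- config$step_scale[[st]]
    v <- if (!is.null(config$drift)) config$drift[[st]] else 0
    dts <- diff(c(c$birth_time, times))
    dts[dts < 0] <- 0
    n <- length(times)
    xy <- matrix(0, n, 2L)
    steps_x <- stats::rnorm(n, 0, scale * sqrt(dts))
    steps_y <- stats::rnorm(n, 0, scale * sqrt(dts))
    if (v > 0) {   # persistent heading, drawn once per cell
      heading <- stats::runif(1L, 0, 2 * pi)
      steps_x <- steps_x + v * dts * cos(heading)
      steps_y <- steps_y + v * dts * sin(heading)
    }
    xy[, 1L] <- start[1L] + cumsum(steps_x)
    xy[, 2L] <- start[2L] + cumsum(steps_y)
    pos[[id]] <- xy[n, ]
    records[[id]] <- cell_record(
      cell_id = id, parent_id = c$parent_id,
      birth_time = c$birth_time, end_time = c$end_time,
      end_event = c$end_event, markers = c$markers,
      trajectory = data.frame(frame = idx - 1L, time = times,
                              x = xy[, 1L], y = xy[, 2L]),
      children = c$children)
  }
  lineage_tree(records, root_type = config$root_type,
               condition = config$condition)
}

# step-scale lookup needs the hidden state carried on the internal record
state_group_of <- function(cells, id, config) cells[[id]]$state

#' Simulate a cohort of colonies
#'
#' Draws `config$n_roots` colonies from one seeded RNG stream. Cell ids are
#' prefixed per colony and unique across the cohort.
#'
#' @param config a [synthetic_config()].
#' @return list with `trees` (list of [lineage_tree()]), `truth` (row-bound
#'   per-cell ground truth with a `colony` column) and `events` (row-bound
#'   bipotent division log with a `colony` column).
#' @export
generate_colonies <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  out_trees <- vector("list", config$n_roots)
  out_truth <- vector("list", config$n_roots)
  out_events <- vector("list", config$n_roots)
  for (i in seq_len(config$n_roots)) {
    col <- generate_colony(config, root_seed = NULL,
                           id_prefix = sprintf("c%03d", i))
    colony <- col$tree$root_id
    col$truth$colony <- colony
    if (nrow(col$events)) col$events$colony <- colony
    out_trees[[i]] <- col$tree
    out_truth[[i]] <- col$truth
    out_events[[i]] <- if (nrow(col$events)) col$events
  }
  list(trees = out_trees,
       truth = {
         tt <- do.call(rbind, out_truth)
         if (is.null(tt))
           tt <- data.frame(cell_id = character(), parent_id = character(),
                            true_state = character(), generation = integer(),
                            birth_time = numeric(), end_time = numeric(),
                            end_event = character(), outcome = character(),
                            from_state = character(), step_scale = numeric(),
                            true_fate_label = character(),
                            colony = character())
         tt
       },
       events = {
         ev <- do.call(rbind, out_events)
         if (is.null(ev))
           ev <- data.frame(parent_id = character(), from_state = character(),
                            generation = integer(), outcome = character(),
                            division_time = numeric(), colony = character())
         ev
       })
}

#' Write a simulated dataset to disk
#'
#' Emits the track TSV, the CTC-style lineage file, the ground-truth and
#' event-log TSVs and a YAML echo of the configuration. Byte-reproducible
#' from (config, seed).
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @param overwrite allow writing into a directory that already contains
#'   dataset files.
#' @return invisible named vector of file paths.
#' @export
generate_dataset <- function(config, dir, overwrite = FALSE) {
  files <- c(tracks = file.path(dir, "tracks.tsv"),
             lineage = file.path(dir, "lineage.txt"),
             truth = file.path(dir, "truth.tsv"),
             events = file.path(dir, "events.tsv"),
             config = file.path(dir, "config.yaml"))
  if (!overwrite && any(file.exists(files)))
    stop("output files exist in ", dir, " (use overwrite = TRUE)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_colonies(config)
  write_tracks(sim$trees, files[["tracks"]])
  write_ctc_lineage(sim$trees, files[["lineage"]])
  write_tsv_table(sim$truth, files[["truth"]])
  write_tsv_table(sim$events, files[["events"]])
  echo_config(config, files[["config"]])
  invisible(files)
}

echo_config <- function(config, file) {
  x <- unclass(config)
  x$outcome_model <- list(shared = x$outcome_model$shared,
                          coefficients = as.list(x$outcome_model$coefficients))
  yaml::write_yaml(x, file)
  invisible(file)
}
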