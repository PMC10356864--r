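#' Generate a full synthetic LDV experiment
#'
#' Emits a complete multi-group experiment — per animal a time-ordered series
#' of runs, each pairing an unstimulated trace with a chirp-response trace
#' from the group's oscillator, plus optional force-step runs — together with
#' a ground-truth table of every generating parameter. Each animal's
#' mechanical state is drawn once from the group's state mixture and persists
#' across its run series. Deterministic given the seed.
#'
#' @param design data frame, one row per group, with columns:
#'   `group` (label), `n_animals`, `runs_per_animal`,
#'   `p_quies`, `p_sso`, `p_transient` (state mixture, summing to 1),
#'   `f_osc` (Hz), `sso_amp` (nm), `noise_rms` (nm) for unstimulated traces;
#'   `f0` (Hz), `zeta`, `accel` (m/s^2) for the chirp responses; optional
#'   `K_un_per_m` (stiffness, uN/m), `force_n` (N) and `n_force_steps`
#'   (force-step runs per animal, default 0).
#' @param seed integer seed.
#' @param fs sampling rate, Hz (default 10000).
#' @param duration section duration, s (default 1).
#' @return List with `runs` (list of [ldv_run()]) and `truth` (data frame of
#'   generating parameters per run).
#' @export
gen_experiment <- function(design, seed = 1, fs = 10000, duration = 1) {
  required <- c("group", "n_animals", "runs_per_animal", "p_quies", "p_sso",
                "p_transient", "f_osc", "sso_amp", "noise_rms", "f0", "zeta",
                "accel")
  if (!is.data.frame(design) || nrow(design) == 0) stop("design must be a non-empty data frame")
  for (i in seq_len(nrow(design))) {
    miss <- required[!required %in% names(design) |
                       vapply(required, function(cn) is.null(design[[cn]][i]) ||
                                is.na(design[[cn]][i]), logical(1))]
    if (length(miss)) stop("design row ", i, ": missing field(s) ",
                           paste(miss, collapse = ", "))
    psum <- design$p_quies[i] + design$p_sso[i] + design$p_transient[i]
    if (abs(psum - 1) > 1e-9) stop("design row ", i, ": state mixture sums to ", psum)
    if (design$n_animals[i] < 1) stop("design row ", i, ": n_animals must be >= 1")
  }
  set.seed(seed)
  chirp <- gen_chirp_stimulus(0, 1000, duration, fs)
  mass_default <- 2e-11 # kg, plausible flagellar apparent mass scale
  runs <- list()
  truth <- list()
  for (gi in seq_len(nrow(design))) {
    g <- design[gi, ]
    n_fsteps <- if (!is.null(g$n_force_steps) && !is.na(g$n_force_steps)) g$n_force_steps else 0L
    for (ai in seq_len(g$n_animals)) {
      animal_id <- sprintf("%s_a%02d", g$group, ai)
      # mechanical state is an animal-level property that persists across a
      # run series (SSO animals sustain their oscillation), so the mixture is
      # sampled once per animal, not independently per run
      states <- rep(sample(c("QUIES", "SSO", "TRANSIENT"), 1,
                           prob = c(g$p_quies, g$p_sso, g$p_transient)),
                    g$runs_per_animal)
      for (ri in seq_len(g$runs_per_animal)) {
        run_id <- sprintf("%s_r%02d", animal_id, ri)
        sspec <- signal_spec(states[ri], f_osc = g$f_osc, amp = g$sso_amp,
                             noise_rms = g$noise_rms, alpha_target = 0.5,
                             fs = fs, duration = duration)
        un <- gen_unstimulated_trace(sspec)
        osc <- oscillator_spec(g$f0, g$zeta, g$accel,
                               noise_rms = 0.05 * g$accel /
                                 (2 * g$zeta * (2 * pi * g$f0)^2) * 1e9)
        st <- gen_chirp_response(osc, chirp, mode = "envelope")
        runs[[length(runs) + 1L]] <- ldv_run(
          run_id, un, st, stimulus_kind = "upchirp",
          backscatter = rep(1, length(st$samples)),
          metadata = list(animal_id = animal_id, group = g$group))
        truth[[length(truth) + 1L]] <- data.frame(
          run_id = run_id, animal_id = animal_id, group = g$group,
          stimulus_kind = "upchirp", true_state = states[ri],
          f_osc = g$f_osc, sso_amp = g$sso_amp, f0 = g$f0, zeta = g$zeta,
          accel = g$accel, K_un_per_m = NA_real_, force_n = NA_real_)
      }
      if (n_fsteps > 0) {
        K <- g$K_un_per_m * 1e-6
        for (fi in seq_len(n_fsteps)) {
          run_id <- sprintf("%s_f%02d", animal_id, fi)
          st <- gen_force_step_response(K, g$force_n, m = mass_default,
                                        zeta = 0.6, duration = duration,
                                        fs = fs, t_on = 0.1,
                                        noise_rms = 0.005 * g$force_n / K * 1e9)
          un <- gen_unstimulated_trace(signal_spec("QUIES", noise_rms = 1,
                                                   fs = fs, duration = duration))
          runs[[length(runs) + 1L]] <- ldv_run(
            run_id, un, st, stimulus_kind = "force_step",
            backscatter = rep(1, length(st$samples)),
            metadata = list(animal_id = animal_id, group = g$group))
          truth[[length(truth) + 1L]] <- data.frame(
            run_id = run_id, animal_id = animal_id, group = g$group,
            stimulus_kind = "force_step", true_state = "QUIES",
            f_osc = NA_real_, sso_amp = NA_real_, f0 = NA_real_,
            zeta = NA_real_, accel = NA_real_,
            K_un_per_m = g$K_un_per_m, force_n = g$force_n)
        }
      }
    }
  }
  list(runs = runs, truth = do.call(rbind, truth))
}

#' Mechanical-state table for a run collection
#'
#' Fits the mixed arcsine-normal amplitude distribution to every unstimulated
#' section, classifies the state, and applies the three-consecutive-run SSO
#' persistence rule within each animal.
#'
#' @param runs list of [ldv_run()] (chirp runs; force-step runs are skipped).
#' @param gof_threshold passed to [classify_state()].
#' @return Data frame (run_id, animal_id, group, alpha, a_min, a_max, mu,
#'   sigma, gof, raw_label, final_label).
#' @export
ldv_state_table <- function(runs, gof_threshold = 0.997) {
  runs <- Filter(function(r) r$stimulus_kind != "force_step" && !is.null(r$unstim),
                 runs)
  rows <- lapply(runs, function(r) {
    fit <- tryCatch(fit_amplitude_distribution(r$unstim$samples),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(run_id = r$run_id,
                        animal_id = r$metadata$animal_id %||% NA_character_,
                        group = r$metadata$group %||% NA_character_,
                        alpha = NA_real_, a_min = NA_real_, a_max = NA_real_,
                        mu = NA_real_, sigma = NA_real_, gof = NA_real_,
                        raw_label = "UNCLASSIFIED"))
    }
    data.frame(run_id = r$run_id,
               animal_id = r$metadata$animal_id %||% NA_character_,
               group = r$metadata$group %||% NA_character_,
               alpha = fit$alpha, a_min = fit$a_min, a_max = fit$a_max,
               mu = fit$mu, sigma = fit$sigma, gof = fit$gof,
               raw_label = classify_state(fit, gof_threshold = gof_threshold))
  })
  out <- do.call(rbind, rows)
  out$final_label <- out$raw_label
  for (aid in unique(out$animal_id)) {
    sel <- out$animal_id == aid
    out$final_label[sel] <- apply_sso_persistence(out$raw_label[sel])
  }
  out
}

#' Spectral-peak table for oscillating runs
#'
#' Runs [spectral_peak()] on the unstimulated sections of runs whose final
#' label is SSO (optionally TRANSIENT too); runs refusing a dominant
#' component are dropped with their error recorded.
#'
#' @param runs list of [ldv_run()].
#' @param states data frame from [ldv_state_table()].
#' @param labels final labels to include (default `"SSO"`).
#' @return Data frame (run_id, animal_id, group, f_sso, amplitude,
#'   resolution).
#' @export
ldv_peak_table <- function(runs, states, labels = "SSO") {
  keep_ids <- states$run_id[states$final_label %in% labels]
  runs <- Filter(function(r) r$run_id %in% keep_ids, runs)
  rows <- lapply(runs, function(r) {
    pk <- tryCatch(spectral_peak(r$unstim), error = function(e) NULL)
    if (is.null(pk)) return(NULL)
    data.frame(run_id = r$run_id,
               animal_id = r$metadata$animal_id %||% NA_character_,
               group = r$metadata$group %||% NA_character_,
               f_sso = pk$f_sso, amplitude = pk$amplitude,
               resolution = pk$resolution)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    out <- data.frame(run_id = character(0), animal_id = character(0),
                      group = character(0), f_sso = numeric(0),
                      amplitude = numeric(0), resolution = numeric(0))
  }
  out
}

#' Stiffness table for force-step runs
#'
#' Applies [steady_state_displacement()] and [steady_state_stiffness()] to
#' every force-step run. The applied force comes from the run metadata or the
#' `forces` argument (named by run_id or a single value).
#'
#' @param runs list of [ldv_run()].
#' @param forces applied force(s) in N: single value or named vector by
#'   run_id.
#' @param step_on,step_off step timing, s.
#' @return Data frame (run_id, animal_id, group, x_ss_nm, force_n,
#'   stiffness_un_per_m, settled).
#' @export
ldv_stiffness_table <- function(runs, forces, step_on = 0.1, step_off = 1) {
  runs <- Filter(function(r) r$stimulus_kind == "force_step", runs)
  rows <- lapply(runs, function(r) {
    force <- if (length(forces) == 1L && is.null(names(forces))) forces else forces[[r$run_id]]
    ss <- steady_state_displacement(r$stim, step_on, step_off)
    K <- if (ss$x_ss > 0) steady_state_stiffness(ss$x_ss, force) else NA_real_
    data.frame(run_id = r$run_id,
               animal_id = r$metadata$animal_id %||% NA_character_,
               group = r$metadata$group %||% NA_character_,
               x_ss_nm = ss$x_ss, force_n = force,
               stiffness_un_per_m = K * 1e6, settled = ss$settled)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(run_id = character(0), animal_id = character(0),
                      group = character(0), x_ss_nm = numeric(0),
                      force_n = numeric(0), stiffness_un_per_m = numeric(0),
                      settled = logical(0))
  }
  out
}
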