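#' Specify a synthetic two-session fMRI cohort
#'
#' Declares the generative model for [generate_cohort()]: N subjects scanned
#' in two sessions, each session a frames-x-regions BOLD-like matrix plus a
#' framewise-displacement (FD) motion trace. The model has three ingredients:
#'
#' * **Stable subject trait.** Each subject draws one AR(1) coefficient
#'   `a_s = ar_coefficient_mean + N(0, subject_sd)`, clipped to (-0.95, 0.95),
#'   shared by both sessions. This is the sole stable trait, so test-retest
#'   reliability of any downstream feature traces back to one knob.
#' * **Community structure.** Regions are partitioned into
#'   `n_communities` contiguous blocks (remainder to the last block). Region
#'   `r`'s series mixes a private AR(1) process with its block's shared AR(1)
#'   signal: `x_r = sqrt(1-L) e_r + sqrt(L) c_g(r)` with
#'   `L = community_loading`, giving within-block correlation ~`L` and
#'   (asymptotically) zero between blocks. Independent white measurement
#'   noise `N(0, session_noise_sd)` is added per session.
#' * **Motion.** Each subject draws a latent motion prevalence
#'   `p_s ~ Beta(motion_prevalence_alpha, motion_prevalence_beta)`: the
#'   expected fraction of corrupted frames. Head movements are short
#'   *events* spanning consecutive frames (a real movement lasts seconds,
#'   not one sample): events start at rate
#'   `q = p_s / (d (1 - p_s))` per clean frame and last `1 + Geom(1/d)`
#'   frames with mean duration `d = motion_event_duration`, which makes the
#'   long-run corrupted-frame fraction equal `p_s`. Corrupted frames have
#'   `FD = 0.2 + Exp(scale_s)` mm (always above the 0.2 mm QC threshold)
#'   with `scale_s = motion_fd_scale + motion_severity_coupling * p_s`:
#'   subjects who move often also move harder, as observed in motion QC of
#'   real cohorts. Clean frames have `FD = |N(0, baseline_fd_sd)|`. Every
#'   corrupted frame injects a global transient
#'   `artifact_gain * (FD - 0.2)` — proportional to the FD *excess* over
#'   the QC threshold, so barely-over-threshold motion leaves almost no
#'   trace while violent movement leaves a large one — into all regions,
#'   decaying geometrically at `artifact_tail_rho` per frame (the
#'   transient-plus-slow, spatially global signal change typical of head
#'   motion; spin-history and related recovery effects persist for seconds
#'   after the movement itself).
#'
#' All randomness flows from `seed` through a subject-major splitting scheme:
#' subject `s` consumes only its own substream, so enlarging the cohort never
#' perturbs earlier subjects' data.
#'
#' @param n_subjects number of subjects.
#' @param n_regions regions per matrix (default 114, a standard functional
#'   parcellation size).
#' @param n_frames frames per session (default 2400: two concatenated
#'   1200-frame runs at TR 0.72 s, ~29 min).
#' @param tr_seconds repetition time, metadata only (default 0.72).
#' @param n_communities number of correlated region blocks (default 4).
#' @param community_loading shared-signal mixing weight in \[0, 1)
#'   (default 0.3; keeps inter-regional synchrony low-to-moderate).
#' @param ar_coefficient_mean population mean AR(1) coefficient in (-1, 1)
#'   (default 0.4, typical of lightly smoothed BOLD).
#' @param subject_sd between-subject SD of the AR coefficient (default 0.15).
#' @param session_noise_sd SD of per-session white measurement noise
#'   (default 0.2).
#' @param motion_prevalence_alpha,motion_prevalence_beta Beta prior on the
#'   per-subject motion prevalence (default Beta(2, 6): mean 25%,
#'   spanning <10% to >40% across a cohort).
#' @param motion_event_duration mean duration of a motion event in frames
#'   (default 3: ~2.2 s at TR 0.72 s).
#' @param motion_fd_scale baseline exponential scale (mm) of FD excess
#'   above 0.2 mm at motion frames (default 0.05).
#' @param motion_severity_coupling added to the FD excess scale per unit of
#'   motion prevalence (mm; default 0.6), coupling how often a subject
#'   moves to how hard they move.
#' @param artifact_gain BOLD transient amplitude per mm of FD excess above
#'   the 0.2 mm threshold (default 20: a 0.4 mm motion frame produces a
#'   ~4 SD global transient, a 0.25 mm frame a ~1 SD one).
#' @param artifact_tail_rho per-frame retention of the decaying artifact
#'   tail in \[0, 1) (default 0.7: time constant ~3 frames, ~2 s at
#'   TR 0.72 s).
#' @param baseline_fd_sd SD (mm) of baseline FD jitter on clean frames
#'   (default 0.04).
#' @param seed integer seed; the cohort is a deterministic function of the
#'   spec including the seed.
#' @return an object of class `cohort_spec` (a validated named list).
#' @seealso [generate_cohort()], [write_cohort()]
#' @export
cohort_spec <- function(n_subjects,
                        n_regions = 114,
                        n_frames = 2400,
                        tr_seconds = 0.72,
                        n_communities = 4,
                        community_loading = 0.3,
                        ar_coefficient_mean = 0.4,
                        subject_sd = 0.15,
                        session_noise_sd = 0.2,
                        motion_prevalence_alpha = 2,
                        motion_prevalence_beta = 6,
                        motion_event_duration = 3,
                        motion_fd_scale = 0.05,
                        motion_severity_coupling = 0.6,
                        artifact_gain = 20,
                        artifact_tail_rho = 0.7,
                        baseline_fd_sd = 0.04,
                        seed = 1L) {
  check_scalar(n_subjects, "n_subjects", lower = 1, integer = TRUE)
  check_scalar(n_regions, "n_regions", lower = 1, integer = TRUE)
  check_scalar(n_frames, "n_frames", lower = 3, integer = TRUE)
  check_scalar(tr_seconds, "tr_seconds", lower = 0, strict_lower = TRUE)
  check_scalar(n_communities, "n_communities", lower = 1, upper = n_regions,
               integer = TRUE)
  check_scalar(community_loading, "community_loading", lower = 0, upper = 1 - 1e-12)
  check_scalar(ar_coefficient_mean, "ar_coefficient_mean", lower = -1 + 1e-12,
               upper = 1 - 1e-12)
  check_scalar(subject_sd, "subject_sd", lower = 0)
  check_scalar(session_noise_sd, "session_noise_sd", lower = 0)
  check_scalar(motion_prevalence_alpha, "motion_prevalence_alpha",
               lower = 0, strict_lower = TRUE)
  check_scalar(motion_prevalence_beta, "motion_prevalence_beta",
               lower = 0, strict_lower = TRUE)
  check_scalar(motion_event_duration, "motion_event_duration", lower = 1)
  check_scalar(motion_fd_scale, "motion_fd_scale", lower = 0, strict_lower = TRUE)
  check_scalar(motion_severity_coupling, "motion_severity_coupling", lower = 0)
  check_scalar(artifact_gain, "artifact_gain", lower = 0)
  check_scalar(artifact_tail_rho, "artifact_tail_rho", lower = 0,
               upper = 1 - 1e-12)
  check_scalar(baseline_fd_sd, "baseline_fd_sd", lower = 0)
  check_scalar(seed, "seed", integer = TRUE)
  spec <- list(n_subjects = as.integer(n_subjects),
               n_regions = as.integer(n_regions),
               n_frames = as.integer(n_frames),
               tr_seconds = tr_seconds,
               n_communities = as.integer(n_communities),
               community_loading = community_loading,
               ar_coefficient_mean = ar_coefficient_mean,
               subject_sd = subject_sd,
               session_noise_sd = session_noise_sd,
               motion_prevalence_alpha = motion_prevalence_alpha,
               motion_prevalence_beta = motion_prevalence_beta,
               motion_event_duration = motion_event_duration,
               motion_fd_scale = motion_fd_scale,
               motion_severity_coupling = motion_severity_coupling,
               artifact_gain = artifact_gain,
               artifact_tail_rho = artifact_tail_rho,
               baseline_fd_sd = baseline_fd_sd,
               seed = as.integer(seed))
  structure(spec, class = "cohort_spec")
}

# Contiguous block assignment; remainder goes to the last block.
region_communities <- function(n_regions, n_communities) {
  block <- n_regions %/% n_communities
  g <- pmin((seq_len(n_regions) - 1L) %/% max(block, 1L) + 1L, n_communities)
  as.integer(g)
}

# Alternating-renewal motion process: events start at rate q per clean
# frame and last 1 + Geom(1/d) frames, so the long-run busy fraction is
# q d / (1 + q d) = p when q = p / (d (1 - p)).
motion_event_frames <- function(T, p, d) {
  m <- logical(T)
  p <- min(p, 0.99)
  if (p <= 0) return(m)
  q <- min(p / (d * (1 - p)), 1)
  t <- 1L
  while (t <= T) {
    if (runif(1) < q) {
      len <- 1L + stats::rgeom(1, 1 / d)
      m[t:min(T, t + len - 1L)] <- TRUE
      t <- t + len
    } else {
      t <- t + 1L
    }
  }
  m
}

# Stationary AR(1) with unit innovations, stationary start.
ar1_series <- function(n, a) {
  e <- rnorm(n)
  x <- numeric(n)
  x[1] <- rnorm(1, sd = 1 / sqrt(1 - a^2))
  for (t in 2:n) x[t] <- a * x[t - 1] + e[t]
  x
}

subject_seed <- function(seed, s) {
  as.integer((as.numeric(seed) + 104729 * s) %% 2147483629L)
}

#' Generate a synthetic two-session cohort
#'
#' Draws the cohort declared by a [cohort_spec()]: per subject a stable AR(1)
#' coefficient and a motion prevalence, then per session the region-mixed
#' series, the FD trace, and the motion artifacts. Deterministic given the
#' spec (including its seed).
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `vg_cohort`: a list with elements
#'   * `spec` — the input spec;
#'   * `series` — nested list, `series[[subject]][[session]]`, each a
#'     frames x regions tibble with region labels `R001...`;
#'   * `motion` — same nesting, each an FD tibble (`frame`, `fd_mm`);
#'   * `truth` — tibble of latent per-subject values (`subject`,
#'     `ar_coefficient`, `motion_probability`);
#'   * `communities` — tibble (`region`, `community`).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    abort("spec must be a cohort_spec object", class = "vgfc_error_validation")
  }
  R <- spec$n_regions; T <- spec$n_frames; G <- spec$n_communities
  gmap <- region_communities(R, G)
  labels <- sprintf("R%03d", seq_len(R))
  series <- vector("list", spec$n_subjects)
  motion <- vector("list", spec$n_subjects)
  truth <- vector("list", spec$n_subjects)
  lam <- spec$community_loading
  for (s in seq_len(spec$n_subjects)) {
    set.seed(subject_seed(spec$seed, s))
    a <- spec$ar_coefficient_mean + rnorm(1, sd = spec$subject_sd)
    a <- min(max(a, -0.95), 0.95)
    p <- rbeta(1, spec$motion_prevalence_alpha, spec$motion_prevalence_beta)
    truth[[s]] <- tibble(subject = s, ar_coefficient = a, motion_probability = p)
    series[[s]] <- vector("list", 2)
    motion[[s]] <- vector("list", 2)
    for (ses in 1:2) {
      comm <- vapply(seq_len(G), function(g) ar1_series(T, a), numeric(T))
      priv <- vapply(seq_len(R), function(r) ar1_series(T, a), numeric(T))
      x <- sqrt(1 - lam) * priv + sqrt(lam) * comm[, gmap, drop = FALSE]
      if (spec$session_noise_sd > 0) {
        x <- x + matrix(rnorm(T * R, sd = spec$session_noise_sd), T, R)
      }
      is_motion <- motion_event_frames(T, p, spec$motion_event_duration)
      fd <- abs(rnorm(T, sd = spec$baseline_fd_sd))
      n_mot <- sum(is_motion)
      if (n_mot > 0) {
        scale_s <- spec$motion_fd_scale + spec$motion_severity_coupling * p
        fd[is_motion] <- 0.2 + rexp(n_mot) * scale_s
        impulse <- numeric(T)
        impulse[is_motion] <- spec$artifact_gain * (fd[is_motion] - 0.2)
        spike <- as.numeric(stats::filter(impulse, spec$artifact_tail_rho,
                                          method = "recursive"))
        x <- x + spike  # recycled column-wise: same global transient everywhere
      }
      colnames(x) <- labels
      series[[s]][[ses]] <- as_tibble(x)
      motion[[s]][[ses]] <- tibble(frame = seq_len(T) - 1L, fd_mm = fd)
    }
  }
  structure(list(spec = spec,
                 series = series,
                 motion = motion,
                 truth = bind_rows(truth),
                 communities = tibble(region = labels, community = gmap)),
            class = "vg_cohort")
}

#' @export
print.vg_cohort <- function(x, ...) {
  cat(sprintf("<vg_cohort> %d subjects x 2 sessions, %d regions x %d frames (TR %.3g s)\n",
              x$spec$n_subjects, x$spec$n_regions, x$spec$n_frames,
              x$spec$tr_seconds))
  cat(sprintf("  communities: %d; seed: %d\n", x$spec$n_communities, x$spec$seed))
  invisible(x)
}

cohort_lookup <- function(cohort, subject, session) {
  if (!inherits(cohort, "vg_cohort")) {
    abort("not a vg_cohort", class = "vgfc_error_validation")
  }
  if (!(subject %in% seq_len(cohort$spec$n_subjects)) || !(session %in% 1:2)) {
    abort(sprintf("unknown subject/session: %s/%s", subject, session),
          class = "vgfc_error_lookup")
  }
  invisible(TRUE)
}

#' Observed motion-corrupted fraction for one scan
#'
#' Fraction of frames in a generated scan whose FD strictly exceeds the
#' threshold; across subjects this tracks the latent `motion_probability`
#' in the cohort truth table.
#'
#' @param cohort a `vg_cohort`.
#' @param subject,session indices (sessions are 1 and 2).
#' @param fd_threshold_mm threshold in mm (default 0.2).
#' @return fraction in \[0, 1\].
#' @export
empirical_motion_fraction <- function(cohort, subject, session,
                                      fd_threshold_mm = 0.2) {
  cohort_lookup(cohort, subject, session)
  motion_fraction(cohort$motion[[subject]][[session]], fd_threshold_mm)
}

#' Per-scan motion summary for a whole cohort
#'
#' @param cohort a `vg_cohort`.
#' @param fd_threshold_mm threshold in mm (default 0.2).
#' @return tibble (`subject`, `session`, `pct_corrupted`) with the percentage
#'   (0-100) of frames above threshold.
#' @export
cohort_motion <- function(cohort, fd_threshold_mm = 0.2) {
  grid <- expand.grid(session = 1:2, subject = seq_len(cohort$spec$n_subjects))
  purrr::map2_dfr(grid$subject, grid$session, function(s, ses) {
    tibble(subject = s, session = ses,
           pct_corrupted = 100 * empirical_motion_fraction(cohort, s, ses,
                                                           fd_threshold_mm))
  }) |> arrange(.data$subject, .data$session)
}

#' Write a cohort to disk in the pipeline's input formats
#'
#' Per subject/session a TSV time-series file and an FD file, plus a
#' manifest (`subject_id`, `session`, `series_path`, `motion_path`) and the
#' latent truth table for validation.
#'
#' @param cohort a `vg_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in seq_len(cohort$spec$n_subjects)) {
    for (ses in 1:2) {
      sp <- file.path(dir, sprintf("sub%03d_ses%d_series.tsv", s, ses))
      mp <- file.path(dir, sprintf("sub%03d_ses%d_fd.tsv", s, ses))
      write_timeseries(cohort$series[[s]][[ses]], sp)
      write_fd(cohort$motion[[s]][[ses]], mp)
      rows[[length(rows) + 1]] <- tibble(subject_id = s, session = ses,
                                         series_path = basename(sp),
                                         motion_path = basename(mp))
    }
  }
  manifest <- bind_rows(rows)
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(cohort$communities, file.path(dir, "communities.tsv"))
  invisible(manifest)
}

#' Read a cohort manifest
#'
#' @param path manifest TSV with columns `subject_id`, `session`,
#'   `series_path`, `motion_path`; relative paths resolve against the
#'   manifest's directory.
#' @return tibble with absolute `series_path`/`motion_path`.
#' @export
read_manifest <- function(path) {
  man <- readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_integer(), session = readr::col_integer(),
    series_path = readr::col_character(), motion_path = readr::col_character()),
    progress = FALSE)
  base <- dirname(path)
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  man |> mutate(series_path = resolve(.data$series_path),
                motion_path = resolve(.data$motion_path))
}
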