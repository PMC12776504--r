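#' @useDynLib pdcnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

band_centres <- c(delta = 2.5, theta = 6, alpha = 10.5, beta = 21, gamma = 40)

# regions whose outgoing connectivity is perturbed in the stroke conditions;
# placed at the head of the rank order so each has downstream targets
key_regions <- c("SMA", "INS", "dorsalA6", "vPM", "M1", "PoG")

rho_default <- 0.97
coupling_gain <- 0.35   # driven-component sd injected per edge (target units)

# AR(2) resonator coefficients for a centre frequency (reference fs 500 Hz)
resonator_coefs <- function(f0, rho, fs = 500) {
  w <- 2 * pi * f0 / fs
  c(2 * rho * cos(w), -rho^2)
}

# variance that a unit-weight lag-1 coupling from a unit-variance resonator
# at f_src injects into a resonator at f_tgt, by spectral integration of
# |H_tgt|^2 |H_src|^2 over frequency
driven_variance_unit <- function(f_src, f_tgt, rho, fs = 500) {
  h2 <- function(ab, om) {
    z1 <- exp(-1i * om); z2 <- exp(-2i * om)
    1 / Mod(1 - ab[1] * z1 - ab[2] * z2)^2
  }
  om <- seq(0, pi, length.out = 2048)
  hs <- h2(resonator_coefs(f_src, rho, fs), om)
  ht <- h2(resonator_coefs(f_tgt, rho, fs), om)
  # innovation variance that gives the source unit stationary variance
  sig2_src <- 1 / (mean(hs) * 2)   # two-sided spectrum folded
  2 * mean(hs * ht) * sig2_src
}

#' Build a condition-specific ground-truth coupling template
#'
#' Constructs the directed coupling graph that drives the synthetic MVAR
#' source model for one study condition. Each of the 14 base regions is given
#' oscillatory self-dynamics (a damped AR(2) resonance, pole radius 0.97)
#' centred in one of the five canonical EEG bands; directed cross-couplings
#' are lag-1 weights between regions. Couplings follow a seeded acyclic rank
#' order over base regions, so the companion matrix keeps spectral radius
#' equal to the pole radius regardless of coupling strength, and every
#' template is mirrored across hemispheres before condition effects are
#' applied (the healthy-control template is exactly hemisphere-symmetric).
#'
#' Condition effects are multiplicative changes (factor 0.6 or 1.4) on the
#' outgoing couplings of targeted regions:
#' \itemize{
#'   \item `stroke_pre` (vs HC): affected SMA and unaffected vPM outflow
#'     down-weighted; affected INS and affected dorsal area 6 outflow
#'     up-weighted (lesion-related disruption plus compensatory increases).
#'   \item `stroke_post` (vs `stroke_pre`): unaffected M1 and affected PoG
#'     outflow up-weighted (rehabilitation-related increases).
#' }
#'
#' @param condition one of `"HC"`, `"stroke_pre"`, `"stroke_post"`.
#' @param lesion_side `"left"` or `"right"` for stroke conditions, `"none"`
#'   for HC.
#' @param seed integer seed; the same seed yields the same base topology in
#'   every condition, so templates are comparable across conditions.
#' @param effect multiplicative effect size applied to targeted outgoing
#'   couplings (default 0.4, i.e. factors 0.6 / 1.4).
#' @return A `coupling_graph`: list with `edges` (data.frame of `source`,
#'   `target`, `band`, `weight`), `condition`, `lesion_side`, `f0` (resonant
#'   frequency in Hz per region label), `rho` (pole radius) and `order`
#'   (MVAR lag order, 5).
#' @examples
#' tpl <- build_cohort_template("HC", "none", seed = 1)
#' head(tpl$edges)
#' @export
build_cohort_template <- function(condition, lesion_side = "none", seed,
                                  effect = 0.4) {
  condition <- match.arg(condition, c("HC", "stroke_pre", "stroke_post"))
  lesion_side <- match.arg(lesion_side, c("none", "left", "right"))
  if (condition == "HC" && lesion_side != "none")
    stop("lesion_side must be 'none' for the HC condition")
  if (condition != "HC" && lesion_side == "none")
    stop("stroke conditions require lesion_side 'left' or 'right'")
  atlas <- region_atlas()
  base <- atlas$base

  local_seed(seed)
  rank_order <- c(sample(key_regions), sample(setdiff(base, key_regions)))
  f0_base <- band_centres[(seq_along(base) - 1L) %% 5L + 1L]
  names(f0_base) <- base
  band_base <- names(band_centres)[(seq_along(base) - 1L) %% 5L + 1L]
  names(band_base) <- base

  # spectral sd amplification per unit coupling weight, for every base pair
  amp <- outer(f0_base, f0_base, Vectorize(function(fs, ft)
    sqrt(driven_variance_unit(fs, ft, rho_default))))
  src <- tgt <- character(0)
  wgt <- numeric(0)
  for (r in seq_len(length(base) - 2L)) {
    s <- rank_order[r]
    # couple only spectrally compatible pairs: the driven component a source
    # injects is amplified by the target's resonance, and where that gain is
    # large the coupling weight needed to keep the driven fraction modest
    # would be too small to estimate. Requiring amplification <= 17.5 keeps
    # every edge both separable (sources stay weakly correlated, so
    # beamforming works) and detectable (weights >= ~0.02)
    pool <- rank_order[(r + 1L):length(base)]
    pool_ok <- pool[band_base[pool] != band_base[s] & amp[s, pool] <= 17.5]
    if (!length(pool_ok)) next
    targets <- sample(pool_ok, min(2L, length(pool_ok)))
    for (t in targets) {
      # calibrate the lag-1 weight so the driven variance injected into the
      # target is a fixed modest fraction of the target's unit own variance
      w <- stats::runif(1, 0.8, 1.2) * coupling_gain / amp[s, t]
      crossed <- stats::runif(1) < 0.3
      if (crossed) {
        src <- c(src, paste0(s, "_L"), paste0(s, "_R"))
        tgt <- c(tgt, paste0(t, "_R"), paste0(t, "_L"))
      } else {
        src <- c(src, paste0(s, "_L"), paste0(s, "_R"))
        tgt <- c(tgt, paste0(t, "_L"), paste0(t, "_R"))
      }
      wgt <- c(wgt, w, w)
    }
  }
  edges <- data.frame(source = src, target = tgt,
                      band = band_base[sub("_[LR]$", "", src)],
                      weight = wgt, row.names = NULL)

  if (condition != "HC") {
    aff <- if (lesion_side == "left") "L" else "R"
    una <- if (aff == "L") "R" else "L"
    scale_out <- function(ed, label, fac) {
      hit <- ed$source == label
      ed$weight[hit] <- ed$weight[hit] * fac
      ed
    }
    edges <- scale_out(edges, paste0("SMA_", aff), 1 - effect)
    edges <- scale_out(edges, paste0("vPM_", una), 1 - effect)
    edges <- scale_out(edges, paste0("INS_", aff), 1 + effect)
    edges <- scale_out(edges, paste0("dorsalA6_", aff), 1 + effect)
    if (condition == "stroke_post") {
      edges <- scale_out(edges, paste0("M1_", una), 1 + effect)
      edges <- scale_out(edges, paste0("PoG_", aff), 1 + effect)
    }
  }

  f0 <- rep(f0_base, 2)
  names(f0) <- atlas$labels
  tpl <- list(edges = edges, condition = condition, lesion_side = lesion_side,
              f0 = f0, rho = 0.97, order = 5L, seed = as.integer(seed))
  class(tpl) <- "coupling_graph"
  rad <- mvar_spectral_radius(template_coefficients(tpl))
  if (rad >= 1) stop("template unstable: companion spectral radius ", rad)
  tpl
}

#' @export
print.coupling_graph <- function(x, ...) {
  cat("coupling_graph: ", x$condition,
      " (lesion ", x$lesion_side, "), ", nrow(x$edges),
      " directed edges, MVAR order ", x$order, "\n", sep = "")
  invisible(x)
}

#' MVAR coefficient matrices realized from a coupling template
#'
#' Diagonal self-dynamics occupy lags 1-2 (damped resonance at each region's
#' centre frequency); cross-couplings occupy lag 1. Entry `(i, j)` of each
#' matrix drives region `i` from region `j`.
#'
#' @param template a `coupling_graph`
#' @param fs sampling rate in Hz (default 500)
#' @return array `R x R x order` of coefficients
#' @export
template_coefficients <- function(template, fs = 500) {
  atlas <- region_atlas()
  R <- length(atlas$labels)
  p <- template$order
  A <- array(0, c(R, R, p))
  for (i in seq_len(R)) {
    w <- 2 * pi * template$f0[i] / fs
    A[i, i, 1] <- 2 * template$rho * cos(w)
    A[i, i, 2] <- -template$rho^2
  }
  si <- atlas_index(atlas, template$edges$source)
  ti <- atlas_index(atlas, template$edges$target)
  for (k in seq_along(si)) A[ti[k], si[k], 1] <- A[ti[k], si[k], 1] + template$edges$weight[k]
  dimnames(A) <- list(atlas$labels, atlas$labels, NULL)
  A
}

#' Companion-matrix spectral radius of an MVAR coefficient array
#'
#' @param coefs array `R x R x p`
#' @return largest eigenvalue modulus of the companion matrix; the system is
#'   stable (stationary) when this is below 1
#' @export
mvar_spectral_radius <- function(coefs) {
  R <- dim(coefs)[1]; p <- dim(coefs)[3]
  comp <- matrix(0, R * p, R * p)
  for (r in seq_len(p)) comp[seq_len(R), ((r - 1) * R + 1):(r * R)] <- coefs[, , r]
  if (p > 1) comp[(R + 1):(R * p), seq_len(R * (p - 1))] <- diag(R * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Simulate source time series from a coupling template
#'
#' Runs the MVAR recursion with seeded unit-variance Gaussian innovations and
#' a discarded burn-in, returning one row per atlas region.
#'
#' @param template a `coupling_graph`
#' @param duration_s recording length in seconds (default 180, the resting
#'   protocol length)
#' @param fs sampling rate in Hz
#' @param seed integer seed for the innovations
#' @param burnin samples discarded before the retained segment (default 1000)
#' @return matrix `regions x (duration_s * fs)` with region-label rownames
#' @export
simulate_mvar <- function(template, duration_s = 180, fs = 500, seed,
                          burnin = 1000L) {
  if (duration_s <= 0) stop("duration_s must be positive")
  coefs <- template_coefficients(template, fs = fs)
  rad <- mvar_spectral_radius(coefs)
  if (rad >= 1) stop("unstable template: spectral radius ", signif(rad, 4))
  R <- dim(coefs)[1]; p <- dim(coefs)[3]
  n <- as.integer(round(duration_s * fs))
  if (n < 10L * p * R)
    stop("duration too short: need at least 10 samples per AR parameter per region")
  local_seed(seed)
  innov <- matrix(stats::rnorm(R * (n + burnin)), R)
  # scale innovations so each region's own AR(2) resonance has unit
  # stationary variance; otherwise slow resonators dominate the cohort
  # variance by orders of magnitude
  a1 <- diag(coefs[, , 1]); a2 <- diag(coefs[, , 2])
  own_var <- (1 - a2) / ((1 + a2) * ((1 - a2)^2 - a1^2))
  innov <- innov / sqrt(own_var)
  flat <- matrix(coefs, R, R * p)
  x <- .mvar_recurse(flat, innov, as.integer(burnin))
  rownames(x) <- dimnames(coefs)[[1]]
  x
}

#' Synthetic sensor lead field
#'
#' Random unit-norm gain columns, one per source region; full column rank is
#' asserted. A synthetic surrogate for a head-model lead field: it preserves
#' the linear mixing structure but none of the anatomy.
#'
#' @param n_sensors number of sensors (>= number of sources)
#' @param atlas a `region_atlas` (default `region_atlas()`)
#' @param seed integer seed
#' @return a `leadfield`: list with `gain` (sensors x sources), `sensor_labels`,
#'   `source_labels`
#' @export
make_leadfield <- function(n_sensors = 64, atlas = region_atlas(), seed) {
  n_src <- length(atlas$labels)
  if (n_sensors < n_src)
    stop("n_sensors (", n_sensors, ") must be >= number of sources (", n_src, ")")
  local_seed(seed)
  G <- matrix(stats::rnorm(n_sensors * n_src), n_sensors, n_src)
  G <- sweep(G, 2, sqrt(colSums(G^2)), "/")
  if (qr(G)$rank < n_src) stop("lead field is column-rank deficient")
  lf <- list(gain = G,
             sensor_labels = sprintf("E%02d", seq_len(n_sensors)),
             source_labels = atlas$labels)
  class(lf) <- "leadfield"
  lf
}

#' Project source activity to sensors with additive white noise
#'
#' Forms `gain %*% sources` and adds spatially white Gaussian sensor noise
#' scaled so the ratio of signal power to noise power matches `snr_db`.
#' `snr_db = Inf` disables the noise.
#'
#' @param sources matrix `sources x samples`
#' @param leadfield a `leadfield`
#' @param snr_db target signal-to-noise ratio in dB
#' @param seed integer seed for the noise
#' @param subject_id,group,session,lesion_side metadata carried on the output
#' @param fs sampling rate in Hz
#' @return an `eeg_recording`: list with `data` (channels x samples), `fs`,
#'   `channel_labels` and the metadata fields
#' @export
project_to_sensors <- function(sources, leadfield, snr_db = 10, seed,
                               subject_id = "S01", group = "HC",
                               session = "single", lesion_side = "none",
                               fs = 500) {
  if (ncol(leadfield$gain) != nrow(sources))
    stop("lead field has ", ncol(leadfield$gain), " source columns but ",
         nrow(sources), " source rows supplied")
  if (is.na(snr_db) || identical(snr_db, -Inf))
    stop("snr_db must be finite or +Inf")
  y <- leadfield$gain %*% sources
  if (is.finite(snr_db)) {
    local_seed(seed)
    p_sig <- mean(y^2)
    p_noise <- p_sig / 10^(snr_db / 10)
    if (p_sig == 0) p_noise <- 1  # pure-noise output with unit variance
    y <- y + matrix(stats::rnorm(length(y), sd = sqrt(p_noise)), nrow(y))
  }
  rec <- list(data = y, fs = fs, channel_labels = leadfield$sensor_labels,
              subject_id = subject_id, group = group, session = session,
              lesion_side = lesion_side)
  class(rec) <- "eeg_recording"
  rec
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("eeg_recording: ", x$subject_id, " [", x$group, "/", x$session,
      ", lesion ", x$lesion_side, "] ", nrow(x$data), " ch x ",
      ncol(x$data), " samples @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Generate a seeded synthetic cohort
#'
#' Produces one recording per subject and condition together with its
#' ground-truth coupling graph and the shared lead field. Stroke subjects are
#' assigned a lesion side (first half left, second half right, the 11/11
#' split at n = 22) and keep the same subject id and lesion side across the
#' pre/post sessions, so paired analyses line up. All per-subject seeds are
#' derived deterministically from the master seed.
#'
#' @param n_per_group subjects per group (default 22)
#' @param conditions subset of `c("HC", "stroke_pre", "stroke_post")`
#' @param seed master integer seed
#' @param duration_s,fs,n_sensors,snr_db forwarded to the generator stages
#' @return list with `recordings` (list of `eeg_recording`), `truth` (list of
#'   `coupling_graph`, parallel to recordings), `leadfield`, `atlas`
#' @export
generate_cohort <- function(n_per_group = 22, conditions = c("HC", "stroke_pre", "stroke_post"),
                            seed, duration_s = 180, fs = 500, n_sensors = 64,
                            snr_db = 10) {
  if (length(conditions) == 0) stop("conditions must be non-empty")
  conditions <- match.arg(conditions, c("HC", "stroke_pre", "stroke_post"),
                          several.ok = TRUE)
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  seed <- as.integer(seed)
  local_seed(seed)
  template_seed <- sample.int(2^31 - 2, 1)
  lf_seed <- sample.int(2^31 - 2, 1)
  sub_seeds <- matrix(sample.int(2^31 - 2, 3L * 2L * n_per_group),
                      nrow = n_per_group)  # innovations + noise per condition
  atlas <- region_atlas()
  lf <- make_leadfield(n_sensors, atlas, seed = lf_seed)
  sides <- rep(c("left", "right"), length.out = n_per_group)
  cond_col <- stats::setNames(seq_along(c("HC", "stroke_pre", "stroke_post")),
                              c("HC", "stroke_pre", "stroke_post"))
  recordings <- list(); truth <- list()
  for (cond in conditions) {
    for (i in seq_len(n_per_group)) {
      if (cond == "HC") {
        sid <- sprintf("HC%02d", i); side <- "none"; sess <- "single"; grp <- "HC"
      } else {
        sid <- sprintf("P%02d", i); side <- sides[i]
        sess <- if (cond == "stroke_pre") "pre" else "post"; grp <- "stroke"
      }
      tpl <- build_cohort_template(cond, side, seed = template_seed)
      cc <- cond_col[[cond]]
      x <- simulate_mvar(tpl, duration_s = duration_s, fs = fs,
                         seed = sub_seeds[i, 2L * cc - 1L])
      # amplitude-normalize each region so every source contributes
      # comparable sensor power; the directed dynamics are unchanged
      x <- x / apply(x, 1, stats::sd)
      rec <- project_to_sensors(x, lf, snr_db = snr_db,
                                seed = sub_seeds[i, 2L * cc],
                                subject_id = sid, group = grp, session = sess,
                                lesion_side = side, fs = fs)
      key <- paste(sid, sess, sep = "_")
      recordings[[key]] <- rec
      truth[[key]] <- tpl
    }
  }
  list(recordings = recordings, truth = truth, leadfield = lf, atlas = atlas)
}
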