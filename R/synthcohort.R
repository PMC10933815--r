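#' Configuration for a synthetic resting-state fMRI cohort
#'
#' Bundles and validates all parameters of the synthetic cohort generator.
#' The generator plants independently controllable within-network temporal
#' synchrony, per-voxel BOLD fluctuation amplitude, between-network latent
#' correlation, a two-block covariation structure across networks, and
#' phenotype columns with known linear effects, so every downstream stage of
#' the pipeline has ground truth to recover.
#'
#' @param n_voxels number of voxels on the (flat) voxel grid.
#' @param n_networks number of networks K (K < n_voxels, K < n_timepoints).
#' @param n_timepoints number of timepoints T per run.
#' @param n_subjects number of subjects S.
#' @param overlap_fraction fraction of each network's voxels shared with the
#'   neighbouring network (partial spatial overlap of maps).
#' @param neg_weight_fraction fraction of within-network voxels carrying
#'   negative map weights (anticorrelated sub-regions).
#' @param synchrony_range length-2 range of the per-subject, per-network
#'   shared-signal fraction rho in (0, 1]: the proportion of each member
#'   voxel's structured variance carried by the common network signal.
#' @param voxel_sd_range length-2 range of the per-subject, per-network voxel
#'   SD scale sigma.
#' @param between_net_corr baseline latent between-network correlation; either
#'   a scalar (exchangeable structure) or a K x K positive semidefinite
#'   matrix.
#' @param fc_coupling in [0, 1]: how strongly the latent between-network
#'   correlation covaries with the planted synchrony. The subject's latent
#'   correlation for networks (j, k) is the baseline scaled by
#'   \code{(1 - fc_coupling) + fc_coupling * rho_j * rho_k / hi^2} (hi the
#'   upper synchrony bound), a Schur-product construction that stays positive
#'   semidefinite. At 0 the baseline is constant across subjects and
#'   networks; above 0 networks and subjects with stronger synchrony also
#'   have stronger connectivity, emulating the empirical coupling of
#'   amplitude and connectivity in resting-state cohorts.
#' @param noise_sd unstructured noise scale, relative to the structured signal
#'   (noise enters inside the sigma scaling so that voxel-SD effects remain
#'   exactly separable from synchrony).
#' @param lowpass_hz low-pass cutoff (Hz) of the latent network signals;
#'   \code{Inf} gives white latent signals.
#' @param tr sampling interval in seconds.
#' @param rho_block_weight weight in [0,1) of the shared block-level latent in
#'   the planted synchrony draws; this is what plants the two-block
#'   (sensory-like / cognitive-like) covariation structure.
#' @param sd_global_weight weight of the shared subject-level latent in the
#'   planted voxel-SD draws; with \code{sd_structure = "global"} voxel-SD
#'   effects covary globally across networks, not by block.
#' @param sd_structure \code{"global"} (default) or \code{"blocks"}:
#'   covariation structure of the planted voxel-SD scales.
#' @param phenotype_spec list of phenotype definitions; each element a list
#'   with fields \code{name}, \code{category}, \code{effect_synchrony},
#'   \code{effect_bold}, \code{missing_rate}, optional \code{cluster} (which
#'   planted cluster's mean the effects act through, default 1).
#' @param confound_spec list of confound definitions; each element a list with
#'   fields \code{name}, \code{effect_phenotype} (added to every phenotype
#'   column) and \code{effect_synchrony} (shift of the planted rho).
#' @param seed integer root seed; all generator randomness derives from it.
#'
#' @return an object of class \code{"sim_config"} (a validated list).
#' @export
sim_config <- function(n_voxels = 420L,
                       n_networks = 6L,
                       n_timepoints = 490L,
                       n_subjects = 100L,
                       overlap_fraction = 0.1,
                       neg_weight_fraction = 0.1,
                       synchrony_range = c(0.2, 0.9),
                       voxel_sd_range = c(0.7, 1.3),
                       between_net_corr = 0.5,
                       fc_coupling = 0.8,
                       noise_sd = 0.5,
                       lowpass_hz = 0.1,
                       tr = 0.735,
                       rho_block_weight = 0.8,
                       sd_global_weight = 0.8,
                       sd_structure = c("global", "blocks"),
                       phenotype_spec = default_phenotype_spec(),
                       confound_spec = default_confound_spec(),
                       seed = 1L) {
  sd_structure <- match.arg(sd_structure)
  cfg <- list(n_voxels = as.integer(n_voxels), n_networks = as.integer(n_networks),
              n_timepoints = as.integer(n_timepoints), n_subjects = as.integer(n_subjects),
              overlap_fraction = overlap_fraction, neg_weight_fraction = neg_weight_fraction,
              synchrony_range = synchrony_range, voxel_sd_range = voxel_sd_range,
              between_net_corr = between_net_corr, fc_coupling = fc_coupling,
              noise_sd = noise_sd,
              lowpass_hz = lowpass_hz, tr = tr,
              rho_block_weight = rho_block_weight, sd_global_weight = sd_global_weight,
              sd_structure = sd_structure,
              phenotype_spec = phenotype_spec, confound_spec = confound_spec,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_voxels >= 1L, cfg$n_networks >= 1L,
            cfg$n_timepoints >= 1L, cfg$n_subjects >= 1L)
  if (cfg$n_networks >= cfg$n_voxels) stop("n_networks must be < n_voxels")
  if (cfg$n_networks >= cfg$n_timepoints) stop("n_networks must be < n_timepoints")
  for (f in c("overlap_fraction", "neg_weight_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(sprintf("%s must lie in [0, 1]", f))
  }
  for (f in c("synchrony_range", "voxel_sd_range")) {
    v <- cfg[[f]]
    if (length(v) != 2L || v[1] > v[2]) stop(sprintf("%s must be an ordered [low, high] pair", f))
  }
  if (cfg$synchrony_range[1] < 0 || cfg$synchrony_range[2] > 1)
    stop("synchrony_range must lie within [0, 1]")
  if (cfg$synchrony_range[2] <= 0)
    stop("synchrony_range must reach above 0 (rho in (0, 1])")
  if (cfg$voxel_sd_range[1] <= 0) stop("voxel_sd_range must be positive")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  bc <- cfg$between_net_corr
  if (is.matrix(bc)) {
    if (!isTRUE(all.equal(bc, t(bc))) || any(diag(bc) != 1))
      stop("between_net_corr matrix must be symmetric with unit diagonal")
    ev <- eigen(bc, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("between_net_corr must be positive semidefinite")
  } else if (abs(bc) >= 1) stop("scalar between_net_corr must lie in (-1, 1)")
  if (cfg$fc_coupling < 0 || cfg$fc_coupling > 1) stop("fc_coupling must lie in [0, 1]")
  for (p in cfg$phenotype_spec) {
    if (p$missing_rate >= 1 || p$missing_rate < 0)
      stop(sprintf("missing_rate for '%s' must lie in [0, 1)", p$name))
  }
  invisible(cfg)
}

#' @rdname sim_config
#' @export
default_phenotype_spec <- function() {
  list(
    list(name = "age_like", category = "demographic",
         effect_synchrony = -0.5, effect_bold = -0.2, missing_rate = 0, cluster = 1L),
    list(name = "systolic_bp_like", category = "cardiovascular",
         effect_synchrony = -0.3, effect_bold = -0.1, missing_rate = 0.1, cluster = 1L),
    list(name = "education_like", category = "sociodemographic",
         effect_synchrony = 0.3, effect_bold = 0, missing_rate = 0.1, cluster = 2L),
    list(name = "null_trait", category = "lifestyle",
         effect_synchrony = 0, effect_bold = 0, missing_rate = 0.2, cluster = 1L)
  )
}

#' @rdname sim_config
#' @export
default_confound_spec <- function() {
  list(
    list(name = "head_motion_like", effect_phenotype = 0.3, effect_synchrony = 0),
    list(name = "scan_time_like", effect_phenotype = 0.2, effect_synchrony = 0)
  )
}

expand_between_net_corr <- function(cfg) {
  K <- cfg$n_networks
  bc <- cfg$between_net_corr
  if (is.matrix(bc)) {
    if (!all(dim(bc) == K)) stop("between_net_corr matrix must be K x K")
    bc
  } else {
    m <- matrix(bc, K, K)
    diag(m) <- 1
    m
  }
}

planted_blocks <- function(K) {
  # two-block partition: first half "sensory-like", rest "cognitive-like"
  c(rep(1L, ceiling(K / 2)), rep(2L, K - ceiling(K / 2)))
}

#' Generate group network spatial maps
#'
#' Lays K networks as blocks of contiguous voxels on a flat grid, with
#' \code{overlap_fraction} of each network's voxels shared with its
#' neighbour and \code{neg_weight_fraction} of member voxels carrying
#' negative Z-weights. Member weights have |Z| above the conventional 3.29
#' mask threshold; non-member entries are exactly zero.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return an N x K numeric matrix of signed Z-stat weights with network
#'   labels as column names; deterministic given \code{cfg$seed}.
#' @export
make_group_maps <- function(cfg) {
  validate_sim_config(cfg)
  N <- cfg$n_voxels; K <- cfg$n_networks
  base <- N %/% K
  if (base < 2L)
    stop(sprintf("infeasible geometry: %d networks of >=2 voxels cannot fit %d voxels", K, N))
  n_ov <- if (K > 1L) round(cfg$overlap_fraction * base) else 0L
  with_seed(derive_seed(cfg$seed, 1L), {
    G <- matrix(0, N, K)
    for (k in seq_len(K)) {
      own <- ((k - 1L) * base + 1L):(k * base)
      idx <- own
      if (k > 1L && n_ov > 0L) idx <- c(own[1L] - seq_len(n_ov), own)
      mag <- stats::runif(length(idx), 3.5, 8)
      sgn <- ifelse(stats::runif(length(idx)) < cfg$neg_weight_fraction, -1, 1)
      G[idx, k] <- mag * sgn
    }
    colnames(G) <- sprintf("net%02d", seq_len(K))
    G
  })
}

#' Generate one subject's BOLD run with planted ground truth
#'
#' Voxel i belonging to network k follows
#' \deqn{x_i = \sigma_i (\sqrt{\rho_k}\,\mathrm{sign}(g_{ki}) s_k +
#'   \sqrt{1-\rho_k}\,\epsilon_i + \mathrm{noise\_sd}\,\eta_i)}
#' where \eqn{s_k} are zero-mean unit-sample-SD latent network signals
#' (band-limited, mixed through the Cholesky factor of the target
#' between-network correlation), \eqn{\rho_k} is the subject's planted
#' synchrony and \eqn{\sigma_i} the planted voxel SD scale. Voxels shared by
#' several networks average their contributions; background voxels carry only
#' idiosyncratic fluctuation. Deterministic given \code{cfg$seed} and
#' \code{subject_index}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param maps group maps from \code{\link{make_group_maps}}.
#' @param subject_index 1-based subject index.
#' @param confound_row optional numeric vector of confound values for this
#'   subject (shifts the planted synchrony by the configured effects).
#' @return list with \code{data} (N x T run), \code{rho} (planted synchrony,
#'   length K), \code{sigma} (planted voxel-SD scale, length K).
#' @export
make_subject <- function(cfg, maps, subject_index, confound_row = NULL) {
  maps <- as_matrix_numeric(maps, "maps")
  K <- cfg$n_networks; N <- cfg$n_voxels; tp <- cfg$n_timepoints
  if (!all(dim(maps) == c(N, K))) stop("maps inconsistent with cfg")
  blocks <- planted_blocks(K)
  lo <- cfg$synchrony_range[1]; hi <- cfg$synchrony_range[2]
  slo <- cfg$voxel_sd_range[1]; shi <- cfg$voxel_sd_range[2]
  w <- cfg$rho_block_weight; wg <- cfg$sd_global_weight
  with_seed(derive_seed(cfg$seed, 1000L + subject_index), {
    u_block <- stats::runif(max(blocks))
    v <- stats::runif(K)
    rho <- lo + (hi - lo) * (w * u_block[blocks] + (1 - w) * v)
    if (!is.null(confound_row)) {
      shift <- sum(vapply(seq_along(cfg$confound_spec), function(q)
        cfg$confound_spec[[q]]$effect_synchrony * confound_row[q], 0))
      rho <- pmin(pmax(rho + shift, min(lo, 1e-3)), 1)
    }
    u_sd <- if (cfg$sd_structure == "global") rep(stats::runif(1L), K) else stats::runif(max(blocks))[blocks]
    v_sd <- stats::runif(K)
    sigma <- slo + (shi - slo) * (wg * u_sd + (1 - wg) * v_sd)

    if (cfg$noise_sd == 0 && all(rho == 0))
      stop("degenerate config: noise_sd = 0 with all planted synchrony 0 yields zero-variance voxels")

    s_raw <- bandlimited_series(K, tp, cfg$lowpass_hz, cfg$tr)
    R <- expand_between_net_corr(cfg)
    if (cfg$fc_coupling > 0) {
      # Schur product of the PSD baseline with the PSD coupling factor
      # (1-c) 11' + (c/hi^2) rho rho', then unit diagonal restored
      cpl <- (1 - cfg$fc_coupling) +
        cfg$fc_coupling * (rho %o% rho) / cfg$synchrony_range[2]^2
      R <- R * cpl
      diag(R) <- 1
    }
    L <- chol(R + diag(1e-10, K))
    s <- row_standardize(t(L) %*% s_raw, what = "latent series")

    eps <- row_standardize(t(matrix(stats::rnorm(N * tp), tp, N)), what = "noise")
    eta <- if (cfg$noise_sd > 0)
      row_standardize(t(matrix(stats::rnorm(N * tp), tp, N)), what = "noise")
    else matrix(0, N, tp)

    member <- maps != 0
    mcount <- rowSums(member)
    sigma_bg <- mean(cfg$voxel_sd_range)
    # mixing weights: sqrt(rho_k) * sign(g_ki), averaged over a voxel's networks
    A <- sweep(sign(maps), 2L, sqrt(rho), `*`) / sqrt(pmax(mcount, 1L))
    sig <- A %*% s
    rho_i <- as.numeric(member %*% rho) / pmax(mcount, 1L)
    idio_scale <- ifelse(mcount > 0L, sqrt(pmax(0, 1 - rho_i)), 1)
    sigma_i <- ifelse(mcount > 0L, as.numeric(member %*% sigma) / pmax(mcount, 1L), sigma_bg)
    x <- sigma_i * (sig + idio_scale * eps + cfg$noise_sd * eta)
    vr <- apply(x, 1L, stats::var)
    if (any(vr == 0))
      stop(sprintf("degenerate run: zero-variance voxels (%s)",
                   paste(utils::head(which(vr == 0), 5L), collapse = ", ")))
    list(data = x, rho = rho, sigma = sigma)
  })
}

#' Generate a full synthetic cohort
#'
#' Runs \code{\link{make_group_maps}}, \code{\link{make_subject}} for every
#' subject, and \code{\link{make_phenotypes}}, returning all pieces plus the
#' planted ground truth.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with elements \code{maps}, \code{runs} (list of N x T
#'   matrices), \code{truth} (list: \code{rho} and \code{sigma} S x K
#'   matrices, \code{between_net_corr}, \code{cluster_assignment},
#'   \code{phenotype_effects}), \code{phenotypes} (data.frame with NAs for
#'   missing), \code{confounds} (S x Q matrix).
#' @export
make_cohort <- function(cfg) {
  validate_sim_config(cfg)
  maps <- make_group_maps(cfg)
  S <- cfg$n_subjects; K <- cfg$n_networks
  Q <- length(cfg$confound_spec)
  conf <- with_seed(derive_seed(cfg$seed, 2L), {
    m <- matrix(stats::rnorm(S * max(Q, 1L)), S, max(Q, 1L))
    if (Q == 0L) m <- m[, 0L, drop = FALSE]
    m
  })
  if (Q > 0L) colnames(conf) <- vapply(cfg$confound_spec, `[[`, "", "name")
  rho <- sigma <- matrix(NA_real_, S, K, dimnames = list(NULL, colnames(maps)))
  runs <- vector("list", S)
  for (s in seq_len(S)) {
    subj <- make_subject(cfg, maps, s, confound_row = if (Q > 0L) conf[s, ] else NULL)
    runs[[s]] <- subj$data
    rho[s, ] <- subj$rho
    sigma[s, ] <- subj$sigma
  }
  truth <- list(rho = rho, sigma = sigma,
                between_net_corr = expand_between_net_corr(cfg),
                cluster_assignment = planted_blocks(K),
                phenotype_effects = cfg$phenotype_spec)
  ph <- make_phenotypes(cfg, truth, conf)
  list(maps = maps, runs = runs, truth = truth,
       phenotypes = ph, confounds = conf)
}

#' Generate phenotype columns with planted linear effects
#'
#' Each phenotype column is a linear combination of the z-scored cluster means
#' of the planted synchrony and voxel-SD scales, plus confound contributions
#' and unit Gaussian noise; missing entries are inserted completely at random
#' at each column's configured rate.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param truth ground-truth list as produced by \code{\link{make_cohort}}
#'   (fields \code{rho}, \code{sigma}, \code{cluster_assignment}).
#' @param confounds S x Q confound matrix (may have zero columns).
#' @return data.frame of phenotype columns with NA for missing entries;
#'   variable categories attached as the \code{"categories"} attribute.
#' @export
make_phenotypes <- function(cfg, truth, confounds) {
  S <- nrow(truth$rho)
  blocks <- truth$cluster_assignment
  with_seed(derive_seed(cfg$seed, 3L), {
    cols <- lapply(cfg$phenotype_spec, function(p) {
      if (p$missing_rate >= 1) stop(sprintf("missing_rate = 1 for '%s'", p$name))
      cl <- p$cluster %||% 1L
      # zero-variance targets contribute nothing rather than NaN
      scale0 <- function(v) {
        s <- stats::sd(v)
        if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
      }
      tgt_s <- rowMeans(truth$rho[, blocks == cl, drop = FALSE])
      tgt_v <- rowMeans(truth$sigma[, blocks == cl, drop = FALSE])
      y <- p$effect_synchrony * scale0(tgt_s) +
        p$effect_bold * scale0(tgt_v) +
        stats::rnorm(S)
      if (ncol(confounds) > 0L) {
        eff <- vapply(cfg$confound_spec, function(q) q$effect_phenotype, 0)
        y <- y + as.numeric(confounds %*% eff)
      }
      y[stats::runif(S) < p$missing_rate] <- NA_real_
      y
    })
    names(cols) <- vapply(cfg$phenotype_spec, `[[`, "", "name")
    out <- as.data.frame(cols)
    attr(out, "categories") <- vapply(cfg$phenotype_spec, `[[`, "", "category")
    out
  })
}

#' Two-voxel phase-offset toy run
#'
#' A deterministic sinusoidal generator for the two-voxel illustration of how
#' a phase offset theta between equally weighted voxels attenuates network
#' amplitude by |cos(theta/2)|.
#'
#' @param theta phase offset in radians.
#' @param n_timepoints timepoints; \code{cycles} whole periods are sampled.
#' @param cycles number of whole periods.
#' @return a 2 x n_timepoints matrix: rows sin(t) and sin(t + theta).
#' @export
two_voxel_phase_run <- function(theta, n_timepoints = 200L, cycles = 4L) {
  t <- 2 * pi * cycles * (0:(n_timepoints - 1L)) / n_timepoints
  rbind(sin(t), sin(t + theta))
}
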