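#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates simulate -> decompose -> netmats -> cluster -> associate as a
#' reproducible run: every stage writes its tables as CSV under
#' \code{out_dir}, a JSON manifest records the configuration, seed, timing
#' and file digests, and a completed stage is reused when \code{resume} is
#' TRUE and its outputs are present.
#'
#' @param config a \code{\link{sim_config}}, a list of \code{sim_config}
#'   arguments, or a path to a YAML/JSON file holding them.
#' @param out_dir output directory (created if needed).
#' @param seed root seed; overrides the config's seed so a pipeline run is
#'   fully determined by (config, seed).
#' @param resume reuse stage outputs already present in \code{out_dir}.
#' @return (invisibly) a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L, resume = FALSE) {
  cfg <- load_sim_config(config)
  cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timing <- list()
  stage_file <- function(...) file.path(out_dir, sprintf(...))

  stage <- function(name, files, compute, reader = NULL) {
    tic <- Sys.time()
    if (resume && all(file.exists(files)) && !is.null(reader)) {
      out <- reader()
    } else {
      out <- compute()
    }
    timing[[name]] <<- as.numeric(difftime(Sys.time(), tic, units = "secs"))
    out
  }

  # -- simulate ------------------------------------------------------------
  sim_files <- stage_file("%s.csv", c("maps", "truth_rho", "truth_sigma",
                                      "phenotypes", "confounds"))
  cohort <- stage("simulate", sim_files, function() {
    co <- make_cohort(cfg)
    write_matrix_csv(co$maps, stage_file("maps.csv"))
    write_matrix_csv(co$truth$rho, stage_file("truth_rho.csv"))
    write_matrix_csv(co$truth$sigma, stage_file("truth_sigma.csv"))
    utils::write.csv(co$phenotypes, stage_file("phenotypes.csv"), row.names = FALSE, na = "")
    write_matrix_csv(co$confounds, stage_file("confounds.csv"))
    co
  })

  # -- decompose -----------------------------------------------------------
  meas_files <- stage_file("%s.csv", c("amplitude", "synchrony", "bold"))
  decomp <- stage("extract", meas_files, function() {
    d <- rsn_decompose(cohort$runs, cohort$maps)
    for (m in c("amplitude", "synchrony", "bold"))
      write_matrix_csv(d[[m]], stage_file("%s.csv", m))
    d
  })

  # -- netmats -------------------------------------------------------------
  nets <- stage("netmats", stage_file("amp_fc_across.csv"), function() {
    nm <- cohort_netmats(decomp)
    across <- across_subject_amp_fc(decomp$amplitude, nm)
    within <- t(vapply(seq_len(decomp$n_subjects), function(s)
      within_subject_amp_fc(decomp$amplitude[s, ],
                            lapply(nm[c("absolute", "positive", "negative")],
                                   function(m) m[s, ])),
      numeric(3)))
    mean_nm <- Reduce(`+`, nm$netmats) / length(nm$netmats)
    write_matrix_csv(mean_nm, stage_file("mean_netmat.csv"))
    utils::write.csv(across, stage_file("amp_fc_across.csv"), row.names = FALSE)
    write_matrix_csv(within, stage_file("amp_fc_within.csv"))
    list(netmats = nm, across = across, within = within, mean_netmat = mean_nm)
  })

  # -- cluster -------------------------------------------------------------
  clus <- stage("cluster", stage_file("cluster_assignment.csv"), function() {
    cov_ <- amplitude_covariation(decomp$amplitude)
    cl <- ward_cluster(cov_, n_clusters = 2L)
    camp <- cluster_amplitude(decomp$amplitude, cl)
    write_matrix_csv(cov_, stage_file("covariation.csv"))
    utils::write.csv(data.frame(network = names(cl$assignment),
                                cluster = cl$assignment),
                     stage_file("cluster_assignment.csv"), row.names = FALSE)
    utils::write.csv(linkage_table(cl), stage_file("linkage.csv"), row.names = FALSE)
    write_matrix_csv(camp, stage_file("cluster_amplitude.csv"))
    list(covariation = cov_, clusters = cl, cluster_amplitude = camp)
  })

  # -- associate -----------------------------------------------------------
  assoc <- stage("associate", stage_file("mass_correlation.csv"), function() {
    ph_dec <- deconfound(as.matrix(cohort$phenotypes), cohort$confounds)
    camp_dec <- deconfound(clus$cluster_amplitude, cohort$confounds)
    mass <- mass_correlate(camp_dec, ph_dec)
    trip <- triplet_correlations(decomp)
    utils::write.csv(mass, stage_file("mass_correlation.csv"), row.names = FALSE)
    write_matrix_csv(cbind(trip$full, trip$partial), stage_file("triplet_correlations.csv"),
                     row_names = TRUE)
    ph_imp <- impute_missing(as.matrix(cohort$phenotypes))
    age <- ph_imp[, 1L]
    sex <- as.numeric(seq_len(nrow(ph_imp)) %% 2L)  # synthetic balanced coding
    reg <- fit_regression_suite(decomp$synchrony,
                                ph_imp[, -1L, drop = FALSE], age = age, sex = sex)
    utils::write.csv(reg, stage_file("regression.csv"), row.names = FALSE)
    list(mass = mass, triplet = trip, regression = reg)
  })

  manifest <- list(
    config = cfg[setdiff(names(cfg), c("phenotype_spec", "confound_spec"))],
    phenotype_names = vapply(cfg$phenotype_spec, `[[`, "", "name"),
    seed = cfg$seed,
    r_version = as.character(getRversion()),
    started = format(t0), finished = format(Sys.time()),
    timing_sec = timing,
    outputs = local({
      fs <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
      as.list(tools::md5sum(fs))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, decomposition = decomp, netmats = nets,
                 clusters = clus, associations = assoc, manifest = manifest,
                 out_dir = out_dir))
}

load_sim_config <- function(config) {
  if (inherits(config, "sim_config")) return(config)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs require the yaml package; use JSON or a list instead")
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a sim_config, a list, or a file path")
  bad <- setdiff(names(config), names(formals(sim_config)))
  if (length(bad)) stop(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")))
  do.call(sim_config, config)
}

#' Render summary figures for a completed pipeline run
#'
#' Writes a multi-page PDF: the reordered covariation heatmap with
#' dendrogram, the distribution of within-subject amplitude-FC correlations,
#' a Manhattan-style -log10 p association profile, the per-network triplet
#' correlations, and the regression-coefficient panel.
#'
#' @param run_dir directory produced by \code{\link{run_pipeline}}.
#' @param file output PDF path (default \code{report.pdf} inside the run
#'   directory).
#' @return the PDF path, invisibly.
#' @export
pipeline_report <- function(run_dir, file = file.path(run_dir, "report.pdf")) {
  need <- file.path(run_dir, c("covariation.csv", "amp_fc_within.csv",
                               "mass_correlation.csv", "triplet_correlations.csv",
                               "regression.csv", "cluster_assignment.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop(sprintf("missing stage outputs: %s", paste(basename(missing), collapse = ", ")))
  cov_ <- read_matrix_csv(file.path(run_dir, "covariation.csv"))
  rownames(cov_) <- colnames(cov_)
  within <- read_matrix_csv(file.path(run_dir, "amp_fc_within.csv"))
  mass <- utils::read.csv(file.path(run_dir, "mass_correlation.csv"))
  trip <- utils::read.csv(file.path(run_dir, "triplet_correlations.csv"), row.names = 1L)
  reg <- utils::read.csv(file.path(run_dir, "regression.csv"))
  assign_ <- utils::read.csv(file.path(run_dir, "cluster_assignment.csv"))

  grDevices::pdf(file, width = 8, height = 6)
  on.exit(grDevices::dev.off())

  cl <- ward_cluster(cov_, n_clusters = max(assign_$cluster))
  ord <- cl$order
  graphics::par(mar = c(6, 6, 3, 1))
  graphics::image(seq_len(ncol(cov_)), seq_len(ncol(cov_)), t(cov_[ord, ord]),
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
                  main = "Amplitude covariation (dendrogram order)")
  graphics::axis(1, seq_len(ncol(cov_)), colnames(cov_)[ord], las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(ncol(cov_)), colnames(cov_)[ord], las = 2, cex.axis = 0.7)
  graphics::plot(cl$hclust, main = "Ward linkage", xlab = "", sub = "")

  graphics::par(mar = c(4, 4, 3, 1))
  graphics::boxplot(as.data.frame(within),
                    names = c("absolute", "positive", "negative"),
                    ylab = "within-subject r (amplitude ~ FC)",
                    main = "Amplitude vs summary FC, per subject")
  graphics::abline(h = 0, lty = 3)

  if (nrow(mass)) {
    m1 <- mass[mass$measure == mass$measure[1L], ]
    graphics::plot(seq_len(nrow(m1)), m1$neglog10p, type = "h", lwd = 3,
                   xaxt = "n", xlab = "", ylab = "-log10 p",
                   main = sprintf("Associations: %s", m1$measure[1L]))
    graphics::axis(1, seq_len(nrow(m1)), m1$variable, las = 2, cex.axis = 0.7)
  } else {
    graphics::plot.new(); graphics::title("no variables pass filters")
  }

  graphics::matplot(trip[, c("r_amp_syn", "r_amp_bold")], type = "b", pch = 19,
                    lty = 1, col = c("darkgreen", "purple"),
                    xlab = "network", ylab = "r with network amplitude",
                    main = "Triplet correlations", ylim = c(-1, 1))
  graphics::legend("bottomleft", c("synchrony", "BOLD amplitude"),
                   col = c("darkgreen", "purple"), lty = 1, pch = 19, bty = "n")

  terms <- setdiff(unique(reg$term), "(Intercept)")
  est <- sapply(terms, function(tm) reg$estimate[reg$term == tm])
  graphics::matplot(est, type = "b", pch = 19, lty = 1,
                    xlab = "network", ylab = "beta",
                    main = "Regression coefficients by network")
  graphics::legend("topright", terms, col = seq_along(terms), lty = 1,
                   pch = 19, bty = "n", cex = 0.7)
  invisible(file)
}
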