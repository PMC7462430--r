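#' Write a connectome dataset as TSV matrices plus a JSON manifest
#'
#' Each connectome goes to one TSV file (plain numeric matrix, no header);
#' `manifest.json` records subject, modality, band, file name and an MD5
#' hash per matrix, plus the band order, so [load_dataset()] can restore the
#' dataset losslessly and verify integrity.
#'
#' @param dataset Dataset tibble (`subject_id`, `modality`, `band`, `conn`).
#' @param dir Output directory (created if missing).
#' @param band_order Optional band order recorded in the manifest.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir, band_order = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- vector("list", nrow(dataset))
  for (k in seq_len(nrow(dataset))) {
    band <- dataset$band[k]
    fname <- sprintf(
      "%s_%s%s.tsv", dataset$subject_id[k], dataset$modality[k],
      if (is.na(band) || band == "") "" else paste0("_", band)
    )
    path <- file.path(dir, fname)
    write.table(format(unclass(dataset$conn[[k]]), digits = 17, trim = TRUE),
      path,
      sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
    )
    entries[[k]] <- list(
      subject_id = dataset$subject_id[k],
      modality = dataset$modality[k],
      band = if (is.na(band)) NULL else band,
      file = fname,
      md5 = unname(tools::md5sum(path))
    )
  }
  manifest <- list(
    format = "connica-dataset",
    band_order = band_order %||% unique(stats::na.omit(dataset$band)),
    connectomes = entries
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

#' Load a connectome dataset from a JSON manifest
#'
#' Reads every matrix listed in the manifest, verifies MD5 hashes (when
#' recorded), enforces symmetry/zero-diagonal invariants, and checks that
#' every subject has exactly one fMRI connectome and one EEG connectome per
#' band, reporting any missing (subject, band) pair by name.
#'
#' @param manifest_path Path to `manifest.json` written by [write_dataset()].
#' @param check_range Passed to [connectome()]; disable for simulated
#'   trait-weight datasets.
#' @return A dataset tibble (`subject_id`, `modality`, `band`, `conn`) with
#'   attribute `band_order`.
#' @export
load_dataset <- function(manifest_path, check_range = FALSE) {
  if (!file.exists(manifest_path)) abort(sprintf("manifest not found: %s", manifest_path))
  manifest <- jsonlite::read_json(manifest_path)
  if (!identical(manifest$format, "connica-dataset")) {
    abort("malformed manifest: missing `format: connica-dataset` marker.")
  }
  dir <- dirname(manifest_path)
  rows <- vector("list", length(manifest$connectomes))
  for (k in seq_along(manifest$connectomes)) {
    e <- manifest$connectomes[[k]]
    path <- file.path(dir, e$file)
    if (!file.exists(path)) abort(sprintf("matrix file missing: %s", e$file))
    if (!is.null(e$md5)) {
      h <- unname(tools::md5sum(path))
      if (!identical(h, e$md5)) abort(sprintf("hash mismatch for %s.", e$file))
    }
    m <- as.matrix(read.table(path, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    if (max(abs(m - t(m))) > 1e-9) {
      abort(sprintf("matrix in %s is not symmetric.", e$file))
    }
    band <- unlist(e$band)
    band <- if (is.null(band) || length(band) == 0L) NA_character_ else as.character(band)
    rows[[k]] <- tibble(
      subject_id = e$subject_id,
      modality = e$modality,
      band = band,
      conn = list(connectome(m, e$modality,
        band = band,
        subject_id = e$subject_id, check_range = check_range
      ))
    )
  }
  dataset <- dplyr::bind_rows(rows)
  band_order <- unlist(manifest$band_order)
  subjects <- unique(dataset$subject_id)
  for (s in subjects) {
    if (sum(dataset$subject_id == s & dataset$modality == "fmri") != 1L) {
      abort(sprintf("subject '%s' lacks exactly one fMRI connectome.", s))
    }
    for (b in band_order) {
      if (sum(dataset$subject_id == s & dataset$band %in% b) != 1L) {
        abort(sprintf("missing (subject '%s', band '%s') EEG connectome.", s, b))
      }
    }
  }
  attr(dataset, "band_order") <- band_order
  dataset
}

#' Write a ground truth as JSON plus trait TSVs
#'
#' @param gt A [ground_truth()].
#' @param dir Output directory.
#' @return The JSON path, invisibly.
#' @export
write_ground_truth <- function(gt, dir) {
  stopifnot(inherits(gt, "ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(gt$traits)) {
    tr <- tibble(
      fmri = gt$traits[[k]]$fmri,
      eeg = gt$traits[[k]]$eeg
    )
    write.table(tr, file.path(dir, sprintf("trait_%02d.tsv", k)),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  meta <- list(
    format = "connica-ground-truth",
    n_traits = length(gt$traits),
    n_regions = gt$n_regions,
    noise_sd = gt$noise_sd,
    seed = gt$seed,
    mixing_dim = dim(gt$mixing),
    mixing = as.vector(gt$mixing),
    partition = if (is.null(gt$partition)) NULL else as.character(gt$partition)
  )
  path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' End-to-end hybrid connICA pipeline
#'
#' Orchestrates one full analysis: harmonize raw EEG connectomes when
#' present, stack the hybrid matrix, run the repeated-ICA decomposition with
#' stability selection, and characterize every robust component (subject and
#' band ICC of its mixing weights, cross-modal edge correlation, and — when
#' a partition is supplied — signed modularity with randomized-null p values
#' for both modality parts). With a second dataset the cross-dataset
#' parameter sweep is run instead of a single decomposition at fixed
#' parameters. All randomness derives from `base_seed`, so identical
#' configurations reproduce bit-identically.
#'
#' @param dataset Dataset tibble or manifest path (see [load_dataset()]).
#' @param partition Optional module labels for modularity testing.
#' @param var_frac,n_ics,n_runs Decomposition parameters
#'   (defaults 0.75, 10, 500).
#' @param occurrence_thr,trait_thr,weight_thr Stability thresholds.
#' @param n_null Null iterations for modularity tests (default 5000).
#' @param base_seed Master seed (default 1).
#' @param band_order Optional band order.
#' @param motion Optional per-subject motion summaries (named numeric
#'   vector, names = subject ids) for Spearman association tests.
#' @param dataset_b Optional second dataset triggering [sweep_parameters()].
#' @param out_dir Optional output directory; components, weights, stats and
#'   a run manifest are written there as TSV/JSON.
#' @return A `connica_report`: `fit`, `component_stats` tibble (one row per
#'   component: ICCs, cross-modal r, modularity Q and p per part),
#'   `modularity` (list of `modularity_test`s), `motion_stats`, `sweep`
#'   (when `dataset_b` given), `config`.
#' @export
run_pipeline <- function(dataset, partition = NULL, var_frac = 0.75, n_ics = 10L,
                         n_runs = 500L, occurrence_thr = 0.75, trait_thr = 0.75,
                         weight_thr = 0.75, n_null = 5000L, base_seed = 1L,
                         band_order = NULL, motion = NULL, dataset_b = NULL,
                         out_dir = NULL) {
  load_if_path <- function(d) if (is.character(d)) load_dataset(d) else d
  dataset <- load_if_path(dataset)
  harmonize_raw <- function(d) {
    raw <- d$modality == "eeg_raw_icoh"
    if (any(raw)) {
      d$conn[raw] <- lapply(d$conn[raw], harmonize_eeg)
      d$modality[raw] <- "eeg_harmonized"
    }
    d
  }
  dataset <- harmonize_raw(dataset)
  config <- list(
    var_frac = var_frac, n_ics = n_ics, n_runs = n_runs,
    occurrence_thr = occurrence_thr, trait_thr = trait_thr,
    weight_thr = weight_thr, n_null = n_null, base_seed = base_seed
  )
  sweep <- NULL
  if (!is.null(dataset_b)) {
    dataset_b <- harmonize_raw(load_if_path(dataset_b))
    sweep <- sweep_parameters(dataset, dataset_b,
      var_fracs = var_frac, ic_counts = n_ics,
      runs_per_cell = n_runs, base_seed = base_seed,
      band_order = band_order,
      occurrence_thr = occurrence_thr, trait_thr = trait_thr,
      weight_thr = weight_thr
    )
    fit <- sweep$fit_a
  } else {
    h <- build_hybrid_matrix(dataset, band_order = band_order)
    fit <- run_connica(h,
      n_ics = n_ics, var_frac = var_frac, n_runs = n_runs,
      base_seed = base_seed, occurrence_thr = occurrence_thr,
      trait_thr = trait_thr, weight_thr = weight_thr
    )
  }
  stats_rows <- list()
  mod_tests <- list()
  motion_rows <- list()
  if (!is.null(fit)) {
    for (i in seq_along(fit$components)) {
      rc <- fit$components[[i]]
      wmat <- mixing_weight_matrix(rc$weights, fit$row_meta)
      icc_s <- icc_oneway(wmat, "subject")
      icc_b <- icc_oneway(wmat, "band")
      xmod <- edge_correlation(
        vectorize_upper(rc$fmri_part),
        vectorize_upper(rc$eeg_part)
      )
      row <- tibble(
        component = i, occurrence = rc$occurrence,
        icc_subject = icc_s$icc, icc_subject_p = icc_s$p,
        icc_band = icc_b$icc, icc_band_p = icc_b$p,
        cross_modal_r = xmod$r, cross_modal_p = xmod$p
      )
      if (!is.null(partition)) {
        mt_f <- modularity_pvalue(rc$fmri_part, partition,
          n_iter = n_null, seed = sub_seed(base_seed, 7000L + i)
        )
        mt_e <- modularity_pvalue(rc$eeg_part, partition,
          n_iter = n_null, seed = sub_seed(base_seed, 8000L + i)
        )
        mod_tests[[sprintf("component%d_fmri", i)]] <- mt_f
        mod_tests[[sprintf("component%d_eeg", i)]] <- mt_e
        row$q_fmri <- mt_f$Q
        row$q_fmri_p <- mt_f$p
        row$q_eeg <- mt_e$Q
        row$q_eeg_p <- mt_e$p
      }
      stats_rows[[i]] <- row
      if (!is.null(motion)) {
        sw <- rowMeans(wmat)
        mo <- motion[rownames(wmat)]
        ms <- motion_spearman(sw, mo)
        motion_rows[[i]] <- tibble(component = i, rho = ms$rho, p = ms$p)
      }
    }
  }
  report <- structure(
    list(
      fit = fit,
      component_stats = dplyr::bind_rows(stats_rows),
      modularity = mod_tests,
      motion_stats = dplyr::bind_rows(motion_rows),
      sweep = sweep,
      config = config
    ),
    class = "connica_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.connica_report <- function(x, ...) {
  cat("<connica_report>\n")
  if (!is.null(x$fit)) print(x$fit)
  if (nrow(x$component_stats)) {
    cat("component stats:\n")
    print(x$component_stats)
  }
  if (!is.null(x$sweep)) print(x$sweep)
  invisible(x)
}

# Persist a report: component matrices + weights as TSV, stats + config as JSON.
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- report$fit
  if (!is.null(fit)) {
    for (i in seq_along(fit$components)) {
      rc <- fit$components[[i]]
      write.table(format(rc$fmri_part, digits = 17, trim = TRUE),
        file.path(out_dir, sprintf("component%d_fmri.tsv", i)),
        sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
      )
      write.table(format(rc$eeg_part, digits = 17, trim = TRUE),
        file.path(out_dir, sprintf("component%d_eeg.tsv", i)),
        sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
      )
    }
    if (length(fit$components)) {
      w_long <- tidy(fit)
      write.table(w_long, file.path(out_dir, "mixing_weights.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE
      )
    }
  }
  stats <- list(
    config = report$config,
    component_stats = report$component_stats,
    motion_stats = report$motion_stats,
    stability = if (!is.null(fit)) {
      lapply(fit$components, function(rc) {
        list(
          occurrence = rc$occurrence, mean_trait_r = rc$mean_trait_r,
          mean_weight_r = rc$mean_weight_r, n_matched = rc$n_matched
        )
      })
    },
    n_converged = if (!is.null(fit)) fit$n_converged,
    sweep_cells = if (!is.null(report$sweep)) report$sweep$cells,
    package_version = as.character(utils::packageVersion("connica"))
  )
  jsonlite::write_json(stats, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows"
  )
  invisible(out_dir)
}
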