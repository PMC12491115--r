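#' Study design
#'
#' The comparison design run over a cohort: which segmentation methods, how
#' many replicates per cell, how many sessions (the repeat a month later) and
#' operators. Replicate, session and operator perturb only the segmentation
#' jitter stream (each gets its own seeded stream); the scan geometry is
#' fixed, matching a design where the same scans are re-segmented.
#'
#' @param methods subset of [segmentation_methods()].
#' @param replicates_per_cell integer >= 1.
#' @param sessions integer >= 1.
#' @param operators integer >= 1.
#' @param seed master seed; per-cell seeds are derived from it by stable
#'   hashing of the cell coordinates, so any cell is replayable in isolation.
#' @return A list of class `study_design`.
#' @export
study_design <- function(methods = segmentation_methods(),
                         replicates_per_cell = 3L, sessions = 2L,
                         operators = 2L, seed = 1L) {
  methods <- match.arg(methods, segmentation_methods(), several.ok = TRUE)
  if (replicates_per_cell < 1 || sessions < 1 || operators < 1)
    stopf("replicates, sessions and operators must all be >= 1")
  structure(list(methods = methods,
                 replicates_per_cell = as.integer(replicates_per_cell),
                 sessions = as.integer(sessions),
                 operators = as.integer(operators), seed = as.integer(seed)),
            class = "study_design")
}

#' Enumerate matching and non-matching pairings
#'
#' Per arch: one matching pairing per participant (their AM vs their PM) and
#' one non-matching pairing per unordered participant pair (AM of the
#' lower-numbered vs PM of the higher-numbered participant — AM always in
#' slot a, PM in slot b, mirroring the forensic AM/PM asymmetry). Six
#' participants give 6 matching and 15 non-matching pairings per arch.
#'
#' @param cohort a `dental_cohort` from [make_cohort()].
#' @return A data frame with columns `participant_a`, `participant_b`,
#'   `arch`, `is_match`.
#' @export
enumerate_pairings <- function(cohort) {
  ids <- sort(unique(vapply(cohort, function(s) s$participant_id, numeric(1))))
  if (length(ids) < 2) stopf("need at least 2 participants")
  rows <- list()
  for (arch in c("upper", "lower")) {
    for (i in ids) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant_a = i, participant_b = i, arch = arch, is_match = TRUE)
    }
    cmb <- utils::combn(ids, 2)
    for (k in seq_len(ncol(cmb))) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant_a = cmb[1, k], participant_b = cmb[2, k], arch = arch,
        is_match = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the comparison study
#'
#' For every pairing x method x replicate x session x operator cell, samples
#' both meshes into point clouds (one seed per cell, shared by the two scans),
#' runs [compare_pair()], and records the final RMS. A failing cell is
#' recorded as an error row and the run continues.
#'
#' @param cohort a `dental_cohort`.
#' @param design a [study_design()].
#' @param sp segmentation parameter template (per-cell seeds are filled in).
#' @param icp ICP parameter template (per-cell seeds are filled in).
#' @param n_points points sampled per scan surface.
#' @param progress emit one progress line per cell to stderr.
#' @return A data frame of comparison records with columns
#'   `participant_a, participant_b, arch, method, replicate, session,
#'   operator, is_match, rms` followed by `cell_seed`, `error`, `timestamp`.
#' @export
run_study <- function(cohort, design = study_design(),
                      sp = segmentation_params(), icp = icp_params(),
                      n_points = 5000L, progress = FALSE) {
  stopifnot(inherits(design, "study_design"))
  pairings <- enumerate_pairings(cohort)
  grid <- expand.grid(pairing = seq_len(nrow(pairings)),
                      method = design$methods,
                      replicate = seq_len(design$replicates_per_cell),
                      session = seq_len(design$sessions),
                      operator = seq_len(design$operators),
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    pr <- pairings[grid$pairing[r], ]
    method <- grid$method[r]
    cell <- c(pr$participant_a, pr$participant_b, pr$arch, method,
              grid$replicate[r], grid$session[r], grid$operator[r])
    cseed <- stable_seed("cell", design$seed, cell)
    rms <- NA_real_
    err <- NA_character_
    res <- tryCatch({
      am <- cohort_scan(cohort, pr$participant_a, pr$arch, "AM")
      pm <- cohort_scan(cohort, pr$participant_b, pr$arch, "PM")
      am_cloud <- sample_surface(am$mesh, n_points, seed = cseed + 1L)
      tmpl <- if (identical(pm$mesh$faces, am$mesh$faces)) am$mesh else NULL
      pm_cloud <- sample_surface(pm$mesh, n_points, seed = cseed + 1L,
                                 template = tmpl)
      sp_cell <- sp
      sp_cell$seed <- as.integer((cseed + 2L) %% .Machine$integer.max)
      icp_cell <- icp
      icp_cell$seed <- as.integer((cseed + 3L) %% .Machine$integer.max)
      compare_pair(am_cloud, pm_cloud, method, sp_cell, icp_cell)
    }, error = function(e) e)
    if (inherits(res, "error")) err <- conditionMessage(res) else rms <- res$rms
    out[[r]] <- data.frame(
      participant_a = pr$participant_a, participant_b = pr$participant_b,
      arch = pr$arch, method = method, replicate = grid$replicate[r],
      session = grid$session[r], operator = grid$operator[r],
      is_match = pr$is_match, rms = rms, cell_seed = cseed, error = err,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      stringsAsFactors = FALSE)
    if (progress)
      message(sprintf("[%d/%d] %s p%sv%s %s rms=%s", r, nrow(grid), method,
                      pr$participant_a, pr$participant_b, pr$arch,
                      if (is.na(rms)) err else sprintf("%.4f", rms)))
  }
  do.call(rbind, out)
}

#' Group summaries of a comparison table
#'
#' Mean RMS and a replicate-based SD per (method, match status, operator).
#' The SD is computed over replicate RMS values within each pairing cell
#' (pairing x arch x session x operator x method) and then averaged across
#' those cells; cells with fewer than 2 replicates report `NA`, never 0.
#'
#' @param table a data frame from [run_study()].
#' @return A data frame with columns `method`, `is_match`, `operator`,
#'   `n`, `mean_rms`, `mean_sd`.
#' @export
summarize_groups <- function(table) {
  if (nrow(table) == 0) stopf("empty comparison table")
  tab <- table[!is.na(table$rms), , drop = FALSE]
  cellkey <- interaction(tab$participant_a, tab$participant_b, tab$arch,
                         tab$method, tab$session, tab$operator, drop = TRUE)
  cell_sd <- tapply(tab$rms, cellkey, function(x)
    if (length(x) < 2) NA_real_ else sd(x))
  cell_first <- tab[!duplicated(cellkey), , drop = FALSE]
  cell_first$cell_sd <- as.numeric(cell_sd[as.character(unique(cellkey))])
  gkey <- function(d) interaction(d$method, d$is_match, d$operator, drop = TRUE)
  g <- gkey(tab)
  means <- tapply(tab$rms, g, mean)
  ns <- tapply(tab$rms, g, length)
  gc <- gkey(cell_first)
  sds <- tapply(cell_first$cell_sd, gc, function(x)
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  keys <- do.call(rbind, strsplit(names(means), "\\."))
  out <- data.frame(method = keys[, 1], is_match = as.logical(keys[, 2]),
                    operator = as.integer(keys[, 3]),
                    n = as.integer(ns), mean_rms = as.numeric(means),
                    mean_sd = as.numeric(sds[names(means)]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$method, out$is_match, out$operator), , drop = FALSE]
}
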