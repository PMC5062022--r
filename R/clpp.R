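# Community-level physiological profiling of BIOLOG phenotype plates.
#
# Readings are endpoint absorbances at 590 nm. Per plate, well A1 is the
# substrate-free blank; the 95 substrate wells are blank-corrected and
# summarised as average well-colour development (AWCD), substrate richness
# (corrected OD strictly above a threshold, default 0.25) and the
# Shannon-Weaver index in natural-log units.

#' Blank-correct a plate reading
#'
#' Subtracts the blank well's OD from every other well and clamps negative
#' values to 0 (negative "activity" is physically meaningless and would break
#' the Shannon proportions).
#'
#' @param od Named numeric vector of per-well ODs (names are well ids).
#' @param blank_well Blank well id, default `"A1"`.
#' @return Named corrected OD vector over the non-blank wells.
#' @export
blank_correct <- function(od, blank_well = "A1") {
  stopifnot(is.numeric(od))
  if (is.null(names(od)) || !blank_well %in% names(od))
    stopf("blank well %s not present in the reading", blank_well)
  out <- od[setdiff(names(od), blank_well)] - od[[blank_well]]
  pmax(out, 0)
}

#' Average well-colour development
#'
#' `AWCD = sum(OD_i) / n`, the mean blank-corrected OD over the substrate
#' wells (n = 95 on a standard PM plate).
#'
#' @param corrected Blank-corrected OD vector.
#' @param n_substrates Divisor; defaults to the vector length.
#' @return AWCD (dimensionless OD).
#' @export
awcd <- function(corrected, n_substrates = length(corrected)) {
  stopifnot(is.numeric(corrected), n_substrates >= 1)
  if (length(corrected) != n_substrates)
    stopf("expected %d substrate wells, got %d", n_substrates, length(corrected))
  sum(corrected) / n_substrates
}

#' Substrate richness
#'
#' The number of substrate wells whose corrected OD is strictly greater than
#' the threshold (default 0.25).
#'
#' @param corrected Blank-corrected OD vector.
#' @param threshold Activity threshold (>= 0).
#' @return Integer count.
#' @export
substrate_richness <- function(corrected, threshold = 0.25) {
  stopifnot(is.numeric(corrected), threshold >= 0)
  sum(corrected > threshold)
}

#' Shannon-Weaver diversity of substrate utilisation
#'
#' `H = -sum(p_i * ln(p_i))` with `p_i = OD_i / sum(OD)`; zero-activity wells
#' contribute nothing (`0 * ln 0 = 0`). Natural-log units (nats).
#'
#' @param corrected Blank-corrected OD vector with at least one positive
#'   entry.
#' @return Shannon index in nats.
#' @export
shannon_index <- function(corrected) {
  stopifnot(is.numeric(corrected), all(corrected >= 0))
  tot <- sum(corrected)
  if (tot <= 0)
    stopf("Shannon index undefined: no substrate shows activity")
  p <- corrected[corrected > 0] / tot
  -sum(p * log(p))
}

#' Per-substrate significance of utilisation differences
#'
#' For each substrate (row), performs a two-sided Welch (unequal-variance)
#' t-test between the replicate ODs of two groups of plates, and reports the
#' t statistic, p value, `-log10(p)` and a significance flag at `alpha`.
#' Either a pairwise comparison of two samples or a one-vs-rest contrast can
#' be expressed through the `groups` factor. When both groups are constant,
#' the degenerate case is resolved directly: equal means give `t = 0, p = 1`;
#' different means give the smallest positive double (so `-log10 p` stays
#' finite). Benjamini-Hochberg correction is available but off by default.
#'
#' @param values Numeric matrix, rows = substrates, columns = replicate
#'   plates.
#' @param groups Factor (or coercible) of length `ncol(values)` with exactly
#'   two levels.
#' @param alpha Significance level, default 0.05.
#' @param p_adjust Either `"none"` (default) or `"BH"`.
#' @return data.frame: `substrate`, group means, `t`, `p`, `neg_log10_p`,
#'   `significant`.
#' @export
substrate_significance <- function(values, groups, alpha = 0.05,
                                   p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  values <- as.matrix(values)
  groups <- as.factor(groups)
  if (length(groups) != ncol(values))
    stopf("groups length (%d) must match the number of columns (%d)",
          length(groups), ncol(values))
  if (nlevels(groups) != 2) stopf("need exactly two groups")
  if (any(table(groups) < 2)) stopf("need >= 2 replicates per group")
  g1 <- groups == levels(groups)[1]
  res <- t(apply(values, 1, function(v) {
    a <- v[g1]; b <- v[!g1]
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    if (se == 0) {
      if (mean(a) == mean(b)) c(mean(a), mean(b), 0, 1)
      else c(mean(a), mean(b), Inf, .Machine$double.xmin)
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
      c(mean(a), mean(b), unname(tt$statistic), tt$p.value)
    }
  }))
  p <- if (p_adjust == "BH") stats::p.adjust(res[, 4], "BH") else res[, 4]
  data.frame(
    substrate = rownames(values) %||% seq_len(nrow(values)),
    mean_1 = res[, 1], mean_2 = res[, 2], t = res[, 3], p = p,
    neg_log10_p = -log10(p), significant = p <= alpha,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Cluster substrates by their utilisation profiles
#'
#' Agglomerative (average-linkage) clustering of substrates on the Euclidean
#' distance between their per-sample utilisation profiles, with the tree cut
#' at a fixed height (default 1.0). Profiles are AWCD-normalised by default
#' (each sample column divided by that sample's mean corrected OD), the usual
#' normalisation before comparing CLPP profiles across samples of different
#' overall activity.
#'
#' @param values Numeric matrix, rows = substrates, columns = samples.
#' @param cut_height Tree cut height, default 1.0.
#' @param normalize Divide each column by its mean (AWCD) first? Default
#'   `TRUE`; columns with zero mean are left as-is.
#' @return Integer cluster assignments named by substrate, with the `hclust`
#'   tree attached as attribute `"tree"`.
#' @export
cluster_substrates <- function(values, cut_height = 1.0, normalize = TRUE) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stopf("need at least two substrates to cluster")
  if (normalize) {
    m <- colMeans(values)
    m[m == 0] <- 1
    values <- sweep(values, 2, m, "/")
  }
  tree <- hclust(dist(values, method = "euclidean"), method = "average")
  cl <- cutree(tree, h = cut_height)
  attr(cl, "tree") <- tree
  cl
}

#' Summarise plate readings into CLPP indices
#'
#' Averages blank-corrected ODs across replicate plates first (one endpoint
#' profile per sample and class), then computes AWCD, substrate richness and
#' the Shannon index per sample and substrate class.
#'
#' @param readings Long-format plate readings as produced by
#'   [simulate_plate()] or [read_plate_csv()]: columns `sample_id`,
#'   `substrate_class`, `plate_id`, `replicate`, `well`, `substrate`, `od`.
#' @param threshold Richness threshold, default 0.25.
#' @param blank_well Blank well id, default `"A1"`.
#' @return data.frame: `sample_id`, `substrate_class`, `n_substrates`,
#'   `awcd`, `richness`, `shannon`.
#' @export
clpp_summary <- function(readings, threshold = 0.25, blank_well = "A1") {
  needed <- c("sample_id", "substrate_class", "plate_id", "replicate",
              "well", "substrate", "od")
  if (!all(needed %in% names(readings)))
    stopf("readings must have columns: %s", paste(needed, collapse = ", "))
  out <- list()
  for (sid in unique(readings$sample_id)) {
    for (cls in unique(readings$substrate_class[readings$sample_id == sid])) {
      sub <- readings[readings$sample_id == sid &
                        readings$substrate_class == cls, ]
      prof <- corrected_profile(sub, blank_well)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, substrate_class = cls, n_substrates = length(prof),
        awcd = awcd(prof),
        richness = substrate_richness(prof, threshold),
        shannon = if (sum(prof) > 0) shannon_index(prof) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Blank-corrected OD per substrate, one column per replicate, for one
# sample/class subset of long-format readings.
corrected_by_replicate <- function(readings, blank_well = "A1") {
  reps <- sort(unique(readings$replicate))
  cols <- lapply(reps, function(r) {
    parts <- list()
    for (pid in unique(readings$plate_id)) {
      plate <- readings[readings$plate_id == pid & readings$replicate == r, ]
      corr <- blank_correct(setNames(plate$od, plate$well), blank_well)
      sub_idx <- plate$substrate[match(names(corr), plate$well)]
      parts[[pid]] <- setNames(corr[!is.na(sub_idx)], sub_idx[!is.na(sub_idx)])
    }
    v <- unlist(unname(parts))
    v[order(as.integer(names(v)))]
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- reps
  mat
}

# Mean blank-corrected OD per substrate across replicate plates, for one
# sample/class subset of long-format readings.
corrected_profile <- function(readings, blank_well = "A1") {
  reps <- list()
  for (pid in unique(readings$plate_id)) {
    for (r in unique(readings$replicate[readings$plate_id == pid])) {
      plate <- readings[readings$plate_id == pid & readings$replicate == r, ]
      od <- setNames(plate$od, plate$well)
      corr <- blank_correct(od, blank_well)
      keep <- !is.na(plate$substrate[match(names(corr), plate$well)])
      sub_idx <- plate$substrate[match(names(corr)[keep], plate$well)]
      reps[[length(reps) + 1L]] <- setNames(corr[keep], sub_idx)
    }
  }
  all_sub <- sort(unique(as.integer(unlist(lapply(reps, names)))))
  prof <- vapply(all_sub, function(s) {
    mean(vapply(reps, function(v) unname(v[as.character(s)]), 0), na.rm = TRUE)
  }, 0)
  setNames(prof, all_sub)
}
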