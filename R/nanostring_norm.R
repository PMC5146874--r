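# nCounter normalization chain:
#   1. background: per lane, mean + 2 * SD of the eight negative-control
#      probes is subtracted; probes at or below the threshold are flagged
#      not-detected (never floored to a small positive value).
#   2. standard curve: per-lane scale factor from the six positive-control
#      probes, s_pos = (cross-lane mean of per-lane positive geometric means)
#      / (lane's geometric mean). A per-lane linear fit of log counts against
#      the known concentration ladder is reported as QC (slope, R^2) but not
#      used for scaling.
#   3. reference genes: the same geometric-mean construction over the
#      reference probes, applied after positive-control scaling.
# Fold changes propagate "nd" (not detected in one condition) and "ND" (not
# detected in either condition) codes instead of numbers.

#' Construct a NanoString nCounter panel
#'
#' @param counts probe x lane matrix of nonnegative raw counts, with probe
#'   row names and lane column names.
#' @param probe_class character per probe: `"endogenous"`, `"positive"`,
#'   `"negative"` or `"reference"`.
#' @param lane_condition character per lane: `"treated"` or `"control"`.
#' @param positive_conc known input amounts for the positive probes, in ladder
#'   order (default the standard 6-point ladder 128 ... 0.125 fM).
#' @return object of class `nanostring_panel`.
#' @export
nanostring_panel <- function(counts, probe_class, lane_condition,
                             positive_conc = c(128, 32, 8, 2, 0.5, 0.125)) {
  counts <- as.matrix(counts)
  stopifnot(is.numeric(counts), all(counts >= 0),
            length(probe_class) == nrow(counts),
            length(lane_condition) == ncol(counts))
  probe_class <- as.character(probe_class)
  lane_condition <- as.character(lane_condition)
  if (!all(probe_class %in% c("endogenous", "positive", "negative", "reference"))) {
    stop("probe_class values must be endogenous/positive/negative/reference")
  }
  if (!all(lane_condition %in% c("treated", "control"))) {
    stop("lane_condition values must be treated/control")
  }
  if (sum(probe_class == "negative") < 2L) {
    stop("need >= 2 negative-control probes (the assay design uses 8)")
  }
  if (sum(probe_class == "positive") < 1L) {
    stop("need >= 1 positive-control probe (the assay design uses 6)")
  }
  if (sum(probe_class == "reference") < 1L) {
    stop("need >= 1 reference probe (the assay design uses 3)")
  }
  npos <- sum(probe_class == "positive")
  if (length(positive_conc) != npos) {
    stop("positive_conc must have one value per positive probe")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("probe_%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("lane_%d", seq_len(ncol(counts)))
  }
  structure(list(counts = counts, probe_class = probe_class,
                 lane_condition = lane_condition,
                 positive_conc = as.numeric(positive_conc)),
            class = "nanostring_panel")
}

#' @export
print.nanostring_panel <- function(x, ...) {
  cl <- table(x$probe_class)
  cat(sprintf(
    "nanostring_panel: %d probes (%s) x %d lanes (%d treated, %d control)\n",
    nrow(x$counts),
    paste(sprintf("%d %s", as.integer(cl), names(cl)), collapse = ", "),
    ncol(x$counts), sum(x$lane_condition == "treated"),
    sum(x$lane_condition == "control")))
  invisible(x)
}

#' Per-lane background threshold
#'
#' Mean plus two sample standard deviations (n - 1 denominator) of the
#' negative-control counts in each lane.
#'
#' @param panel a [nanostring_panel()].
#' @param lane optional lane name or index; default all lanes.
#' @return named numeric vector of thresholds `B`.
#' @export
background_threshold <- function(panel, lane = NULL) {
  stopifnot(inherits(panel, "nanostring_panel"))
  neg <- panel$counts[panel$probe_class == "negative", , drop = FALSE]
  if (nrow(neg) < 2L) stop("background SD undefined with < 2 negative probes")
  B <- apply(neg, 2L, function(x) mean(x) + 2 * sd(x))
  if (!is.null(lane)) B[lane] else B
}

#' Background subtraction with detection flags
#'
#' Counts strictly above the lane threshold `B` become `count - B`; counts at
#' or below it become `NA` (not detected). No flooring is applied.
#'
#' @param panel a [nanostring_panel()].
#' @return probe x lane matrix of corrected values with `NA` for not-detected
#'   entries; the thresholds are attached as attribute `"B"`.
#' @export
subtract_background <- function(panel) {
  stopifnot(inherits(panel, "nanostring_panel"))
  B <- background_threshold(panel)
  corrected <- sweep(panel$counts, 2L, B, "-")
  corrected[sweep(panel$counts, 2L, B, "<=")] <- NA_real_
  attr(corrected, "B") <- B
  corrected
}

geomean <- function(x) exp(mean(log(x)))

#' Positive-control (standard-curve) scale factors
#'
#' For each lane, the geometric mean of the background-corrected
#' positive-control values; the scale factor is the across-lane arithmetic
#' mean of those geometric means divided by the lane's own, so identical lanes
#' get factor 1 and a lane with doubled positives gets half the factor.
#'
#' @param panel a [nanostring_panel()].
#' @param corrected background-corrected matrix (default
#'   `subtract_background(panel)`).
#' @return named numeric vector `s_pos` (one factor per lane); the per-lane
#'   geometric means are attached as attribute `"geomeans"`.
#' @export
positive_control_scale <- function(panel, corrected = subtract_background(panel)) {
  stopifnot(inherits(panel, "nanostring_panel"))
  pos <- corrected[panel$probe_class == "positive", , drop = FALSE]
  if (anyNA(pos) || any(pos <= 0)) {
    bad <- which(apply(pos, 2L, function(x) anyNA(x) || any(x <= 0)))
    stop("positive-control probe(s) not detected above background in lane(s): ",
         paste(colnames(pos)[bad], collapse = ", "))
  }
  g <- apply(pos, 2L, geomean)
  s <- mean(g) / g
  attr(s, "geomeans") <- g
  s
}

#' Reference-gene scale factors
#'
#' Applied after positive-control scaling: the same geometric-mean
#' construction over the reference probes' scaled values.
#'
#' @param panel a [nanostring_panel()].
#' @param scaled probe x lane matrix after background subtraction and
#'   positive-control scaling.
#' @return named numeric vector `s_ref`.
#' @export
reference_gene_scale <- function(panel, scaled) {
  stopifnot(inherits(panel, "nanostring_panel"))
  ref <- scaled[panel$probe_class == "reference", , drop = FALSE]
  if (anyNA(ref) || any(ref <= 0)) {
    idx <- which(is.na(ref) | ref <= 0, arr.ind = TRUE)
    stop("reference probe not detected: probe ",
         rownames(ref)[idx[1L, 1L]], " in lane ", colnames(ref)[idx[1L, 2L]])
  }
  g <- apply(ref, 2L, geomean)
  mean(g) / g
}

#' Standard-curve QC fit
#'
#' Per-lane least-squares fit of `log2(corrected positive count)` against
#' `log2(known concentration)`; reported as QC only (slope near 1 and high
#' R^2 indicate counts within the linear dynamic range of the ladder).
#'
#' @param panel a [nanostring_panel()].
#' @param corrected background-corrected matrix.
#' @return data frame `lane`, `slope`, `r_squared`.
#' @export
standard_curve_qc <- function(panel, corrected = subtract_background(panel)) {
  stopifnot(inherits(panel, "nanostring_panel"))
  pos <- corrected[panel$probe_class == "positive", , drop = FALSE]
  x <- log2(panel$positive_conc)
  out <- lapply(colnames(pos), function(lane) {
    y <- log2(pos[, lane])
    ok <- is.finite(y)
    if (sum(ok) < 2L) return(data.frame(lane = lane, slope = NA_real_,
                                        r_squared = NA_real_))
    fit <- lsfit(x[ok], y[ok])
    data.frame(lane = lane, slope = fit$coefficients[["X"]],
               r_squared = cor(x[ok], y[ok])^2)
  })
  do.call(rbind, out)
}

#' Full nCounter normalization chain
#'
#' Background subtraction, positive-control (standard-curve) scaling and
#' reference-gene scaling, in that order. A normalized value is
#' `(raw - B) * s_pos * s_ref` when `raw > B`, else not detected (`NA`).
#'
#' @param panel a [nanostring_panel()].
#' @return object of class `normalized_panel`: list with `values` (probe x
#'   lane, `NA` = not detected), `detected` (logical matrix), `B`, `s_pos`,
#'   `s_ref`, `qc` (standard-curve fits), `probe_class`, `lane_condition`.
#' @export
normalize_nanostring <- function(panel) {
  stopifnot(inherits(panel, "nanostring_panel"))
  corrected <- subtract_background(panel)
  s_pos <- positive_control_scale(panel, corrected)
  scaled <- sweep(corrected, 2L, s_pos, "*")
  s_ref <- reference_gene_scale(panel, scaled)
  values <- sweep(scaled, 2L, s_ref, "*")
  structure(list(values = values, detected = !is.na(values),
                 B = attr(corrected, "B"), s_pos = s_pos, s_ref = s_ref,
                 qc = standard_curve_qc(panel, corrected),
                 probe_class = panel$probe_class,
                 lane_condition = panel$lane_condition),
            class = "normalized_panel")
}

#' @export
print.normalized_panel <- function(x, ...) {
  cat(sprintf(
    "normalized_panel: %d probes x %d lanes; %d not-detected value(s)\n",
    nrow(x$values), ncol(x$values), sum(!x$detected)))
  cat("  B:", paste(signif(x$B, 4), collapse = " "), "\n")
  cat("  s_pos * s_ref:", paste(signif(x$s_pos * x$s_ref, 4), collapse = " "), "\n")
  invisible(x)
}

#' Per-probe log2 fold change from a normalized panel
#'
#' Default estimator is the log2 ratio of condition means over detected
#' replicates (`method = "ratio_of_means"`); the mean of per-replicate log
#' ratios is available as `"mean_of_logs"` (it pairs replicates by order and
#' requires equal detected replicate numbers; otherwise the ratio of means is
#' used for that probe). Probes with no detected treated replicate get status
#' `"nd-treated"`, none detected in control `"nd-control"`, none in either
#' `"ND"`; their `log2fc` is `NA`.
#'
#' @param norm a `normalized_panel` from [normalize_nanostring()].
#' @param method fold-change estimator (see above).
#' @param classes probe classes included (default endogenous only).
#' @return data frame `probe`, `mean_treated`, `mean_control`, `log2fc`,
#'   `status` (`"ok"`, `"nd-treated"`, `"nd-control"`, `"ND"`).
#' @export
nanostring_log2fc <- function(norm, method = c("ratio_of_means", "mean_of_logs"),
                              classes = "endogenous") {
  stopifnot(inherits(norm, "normalized_panel"))
  method <- match.arg(method)
  treated <- norm$lane_condition == "treated"
  control <- norm$lane_condition == "control"
  if (!any(treated) || !any(control)) {
    stop("panel must contain both treated and control lanes")
  }
  keep <- norm$probe_class %in% classes
  vals <- norm$values[keep, , drop = FALSE]
  out <- lapply(rownames(vals), function(p) {
    vt <- vals[p, treated]
    vc <- vals[p, control]
    det_t <- vt[!is.na(vt)]
    det_c <- vc[!is.na(vc)]
    status <- if (!length(det_t) && !length(det_c)) "ND"
      else if (!length(det_t)) "nd-treated"
      else if (!length(det_c)) "nd-control"
      else "ok"
    mt <- if (length(det_t)) mean(det_t) else NA_real_
    mc <- if (length(det_c)) mean(det_c) else NA_real_
    lfc <- NA_real_
    if (status == "ok") {
      if (method == "mean_of_logs" && length(det_t) == length(det_c)) {
        lfc <- mean(log2(det_t / det_c))
      } else {
        lfc <- log2(mt / mc)
      }
    }
    data.frame(probe = p, mean_treated = mt, mean_control = mc,
               log2fc = lfc, status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read an nCounter panel from TSV files
#'
#' @param counts_tsv probe x lane counts (first column `probe`, one column
#'   per lane).
#' @param probe_tsv probe metadata: `probe_id`, `class`, optional
#'   `known_conc` for positive probes.
#' @param lane_tsv lane metadata: `lane_id`, `condition`, optional
#'   `replicate`.
#' @return a [nanostring_panel()].
#' @export
read_nanostring_panel <- function(counts_tsv, probe_tsv, lane_tsv) {
  counts <- read_tsv_manifest(counts_tsv)
  probes <- read_tsv_manifest(probe_tsv)
  lanes <- read_tsv_manifest(lane_tsv)
  stopifnot(names(counts)[1L] == "probe",
            all(c("probe_id", "class") %in% names(probes)),
            all(c("lane_id", "condition") %in% names(lanes)))
  m <- as.matrix(counts[, -1L, drop = FALSE])
  rownames(m) <- counts$probe
  m <- m[, as.character(lanes$lane_id), drop = FALSE]
  cls <- probes$class[match(rownames(m), probes$probe_id)]
  if (anyNA(cls)) stop("probe(s) missing from metadata: ",
                       paste(head(rownames(m)[is.na(cls)], 5L), collapse = ", "))
  conc <- if ("known_conc" %in% names(probes)) {
    probes$known_conc[match(rownames(m)[cls == "positive"], probes$probe_id)]
  } else {
    c(128, 32, 8, 2, 0.5, 0.125)[seq_len(sum(cls == "positive"))]
  }
  nanostring_panel(m, cls, as.character(lanes$condition), conc)
}

#' Write an nCounter panel as TSV files
#'
#' Inverse of [read_nanostring_panel()].
#'
#' @param panel a [nanostring_panel()].
#' @param counts_tsv,probe_tsv,lane_tsv output paths.
#' @return `counts_tsv`, invisibly.
#' @export
write_nanostring_panel <- function(panel, counts_tsv, probe_tsv, lane_tsv) {
  stopifnot(inherits(panel, "nanostring_panel"))
  counts <- data.frame(probe = rownames(panel$counts), panel$counts,
                       stringsAsFactors = FALSE, check.names = FALSE)
  write_tsv_manifest(counts, counts_tsv)
  conc <- rep(NA_real_, nrow(panel$counts))
  conc[panel$probe_class == "positive"] <- panel$positive_conc
  write_tsv_manifest(data.frame(probe_id = rownames(panel$counts),
                                class = panel$probe_class, known_conc = conc,
                                stringsAsFactors = FALSE), probe_tsv)
  lanes <- data.frame(lane_id = colnames(panel$counts),
                      condition = panel$lane_condition,
                      replicate = stats::ave(seq_along(panel$lane_condition),
                                             panel$lane_condition,
                                             FUN = seq_along),
                      stringsAsFactors = FALSE)
  write_tsv_manifest(lanes, lane_tsv)
  invisible(counts_tsv)
}

#' Write a normalized panel as TSV
#'
#' Endogenous values with `nd` codes, plus a QC table (`B`, `s_pos`, `s_ref`,
#' standard-curve slope and R^2 per lane).
#'
#' @param norm a `normalized_panel`.
#' @param values_path normalized-values TSV path.
#' @param qc_path optional QC TSV path.
#' @param manifest extra manifest entries.
#' @return `values_path`, invisibly.
#' @export
write_normalized_panel <- function(norm, values_path, qc_path = NULL,
                                   manifest = list()) {
  stopifnot(inherits(norm, "normalized_panel"))
  vals <- norm$values
  chr <- format(round(vals, 6), trim = TRUE)
  chr[is.na(vals)] <- "nd"
  df <- data.frame(probe = rownames(vals), probe_class = norm$probe_class,
                   chr, stringsAsFactors = FALSE, check.names = FALSE)
  write_tsv_manifest(df, values_path, manifest)
  if (!is.null(qc_path)) {
    qc <- norm$qc
    qc$B <- norm$B[qc$lane]
    qc$s_pos <- norm$s_pos[qc$lane]
    qc$s_ref <- norm$s_ref[qc$lane]
    qc$condition <- norm$lane_condition[match(qc$lane, colnames(norm$values))]
    write_tsv_manifest(qc, qc_path, manifest)
  }
  invisible(values_path)
}
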