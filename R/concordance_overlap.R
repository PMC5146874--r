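# Cross-platform fold-change concordance (Pearson r, least-squares line,
# sign concordance) and gene-set overlap / direction analyses.

#' Cross-platform fold-change concordance
#'
#' Pearson correlation, least-squares line and sign concordance between two
#' log2 fold-change vectors measured on the same genes by two platforms
#' (e.g. RNA-Seq and nCounter). Not-detected values (`NA`) are excluded by
#' default; `nd_policy = "zero"` substitutes 0 instead (an absent signal
#' treated as no change).
#'
#' @param paired data frame with columns `gene_id`, `log2fc_a`, `log2fc_b`
#'   (`NA` = not detected / not significant).
#' @param nd_policy `"exclude"` (default) or `"zero"`.
#' @return object of class `concordance_report`: list with `n_pairs`,
#'   `pearson_r`, `r_squared`, `slope`, `intercept` (b on a),
#'   `sign_concordance` (fraction of pairs with matching nonzero signs among
#'   pairs where both are nonzero) and `excluded_nd`.
#' @export
platform_concordance <- function(paired, nd_policy = c("exclude", "zero")) {
  nd_policy <- match.arg(nd_policy)
  stopifnot(all(c("gene_id", "log2fc_a", "log2fc_b") %in% names(paired)))
  if (anyDuplicated(paired$gene_id)) stop("duplicated gene_id in paired table")
  a <- as.numeric(paired$log2fc_a)
  b <- as.numeric(paired$log2fc_b)
  nd <- is.na(a) | is.na(b)
  if (nd_policy == "zero") {
    a[is.na(a)] <- 0
    b[is.na(b)] <- 0
    excluded <- 0L
  } else {
    a <- a[!nd]
    b <- b[!nd]
    excluded <- sum(nd)
  }
  if (length(a) < 2L) stop("fewer than 2 complete pairs after nd handling")
  if (sd(a) == 0 || sd(b) == 0) stop("zero variance in a fold-change vector")
  r <- cor(a, b)
  fit <- lsfit(a, b)
  both_signed <- sign(a) != 0 & sign(b) != 0
  structure(list(
    n_pairs = length(a), pearson_r = r, r_squared = r^2,
    slope = fit$coefficients[["X"]],
    intercept = fit$coefficients[["Intercept"]],
    sign_concordance = if (any(both_signed)) {
      mean(sign(a[both_signed]) == sign(b[both_signed]))
    } else NA_real_,
    excluded_nd = excluded, nd_policy = nd_policy
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(paste0(
    "concordance_report: n = %d pairs (%d nd excluded, policy '%s')\n",
    "  Pearson r = %.4f, R^2 = %.4f, b = %.3f a %+.3f, sign concordance = %.3f\n"),
    x$n_pairs, x$excluded_nd, x$nd_policy, x$pearson_r, x$r_squared,
    x$slope, x$intercept, x$sign_concordance))
  invisible(x)
}

#' Gene-set overlap with direction breakdown
#'
#' Intersects two DE tables and, where both carry log2 fold changes, splits
#' the intersection by direction agreement (sign of log2FC; zero fold changes
#' carry no direction and are excluded from the same/opposite counts). An
#' optional hypergeometric p-value for the overlap size is computed when a
#' universe size is supplied.
#'
#' @param table_a,table_b data frames with `gene_id` and optionally `log2fc`.
#' @param universe_size optional number of genes in the shared universe, for
#'   the overlap-size hypergeometric upper tail `P(X >= observed)`.
#' @return object of class `overlap_report`: list with `n_a`, `n_b`,
#'   `n_intersect`, `n_same_direction`, `n_opposite`, `n_undirected`,
#'   `intersect_ids`, and `p_overlap` (or `NA`).
#' @export
set_overlap <- function(table_a, table_b, universe_size = NULL) {
  for (t in list(table_a, table_b)) {
    stopifnot("gene_id" %in% names(t))
    if (anyDuplicated(t$gene_id)) stop("duplicated gene_id within a table")
  }
  ids <- intersect(table_a$gene_id, table_b$gene_id)
  n_same <- n_opp <- n_undir <- 0L
  if (length(ids) && "log2fc" %in% names(table_a) &&
      "log2fc" %in% names(table_b)) {
    sa <- sign(table_a$log2fc[match(ids, table_a$gene_id)])
    sb <- sign(table_b$log2fc[match(ids, table_b$gene_id)])
    directed <- !is.na(sa) & !is.na(sb) & sa != 0 & sb != 0
    n_same <- sum(directed & sa == sb)
    n_opp <- sum(directed & sa != sb)
    n_undir <- length(ids) - n_same - n_opp
  } else {
    n_undir <- length(ids)
  }
  p_overlap <- NA_real_
  if (!is.null(universe_size)) {
    stopifnot(universe_size >= length(union(table_a$gene_id, table_b$gene_id)))
    p_overlap <- phyper(length(ids) - 1L, nrow(table_a),
                        universe_size - nrow(table_a), nrow(table_b),
                        lower.tail = FALSE)
  }
  structure(list(n_a = nrow(table_a), n_b = nrow(table_b),
                 n_intersect = length(ids), n_same_direction = n_same,
                 n_opposite = n_opp, n_undirected = n_undir,
                 intersect_ids = ids, p_overlap = p_overlap),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(paste0(
    "overlap_report: |A| = %d, |B| = %d, |A intersect B| = %d\n",
    "  same direction = %d, opposite = %d, undirected = %d"),
    x$n_a, x$n_b, x$n_intersect, x$n_same_direction, x$n_opposite,
    x$n_undirected))
  if (!is.na(x$p_overlap)) {
    cat(sprintf(", P(overlap >= obs) = %.3g", x$p_overlap))
  }
  cat("\n")
  invisible(x)
}

#' Cross-species ortholog direction concordance
#'
#' For each source gene (e.g. an Arabidopsis gene from a curated
#' cytokinin-response list) with at least one mapped ortholog, classifies it
#' by whether any ortholog is differentially expressed in the same direction
#' (precedence: same > opposite > not-DE). Source genes without orthologs are
#' excluded from the denominator.
#'
#' @param ortholog_map data frame `source_id`, `target_id` (many-to-many).
#' @param de_source DE table for the source species (`gene_id`, `log2fc`).
#' @param de_target DE table for the target species (`gene_id`, `log2fc`).
#' @return list with counts `n_source`, `n_with_ortholog`, `n_same_direction`,
#'   `n_opposite_direction`, `n_not_de`, and the corresponding fractions of
#'   `n_with_ortholog` (`frac_with_ortholog` is of `n_source`).
#' @export
ortholog_concordance <- function(ortholog_map, de_source, de_target) {
  stopifnot(all(c("source_id", "target_id") %in% names(ortholog_map)),
            all(c("gene_id", "log2fc") %in% names(de_source)),
            all(c("gene_id", "log2fc") %in% names(de_target)))
  if (nrow(ortholog_map) == 0L) stop("empty ortholog map")
  src_ids <- unique(de_source$gene_id)
  src_sign <- sign(de_source$log2fc[match(src_ids, de_source$gene_id)])
  tgt_sign <- setNames(sign(de_target$log2fc), de_target$gene_id)
  mapped <- split(as.character(ortholog_map$target_id),
                  as.character(ortholog_map$source_id))
  classes <- vapply(seq_along(src_ids), function(i) {
    orths <- mapped[[src_ids[i]]]
    if (is.null(orths) || !length(orths)) return("no_ortholog")
    s <- tgt_sign[orths]
    s <- s[!is.na(s) & s != 0]
    if (!length(s) || src_sign[i] == 0) return("not_de")
    if (any(s == src_sign[i])) "same" else "opposite"
  }, character(1L))
  n_with <- sum(classes != "no_ortholog")
  if (n_with == 0L) stop("no source gene has a mapped ortholog")
  list(n_source = length(src_ids),
       n_with_ortholog = n_with,
       n_same_direction = sum(classes == "same"),
       n_opposite_direction = sum(classes == "opposite"),
       n_not_de = sum(classes == "not_de"),
       frac_with_ortholog = n_with / length(src_ids),
       frac_same_direction = sum(classes == "same") / n_with,
       frac_opposite_direction = sum(classes == "opposite") / n_with,
       frac_not_de = sum(classes == "not_de") / n_with)
}

#' Bundled cross-platform validation panel
#'
#' Log2 fold changes for a 32-gene benzyladenine-response validation panel
#' measured in rice roots and shoots by both RNA-Seq and the nCounter assay
#' (published study data shipped with the package). `NA` marks genes not
#' significant on RNA-Seq in that tissue; the strings `"nd"`/`"ND"` in the
#' source file mark probes below nCounter background in one/both conditions
#' and are returned as `NA` with the code kept in `root_nano_code` /
#' `shoot_nano_code`.
#'
#' @return data frame with columns `gene_id`, `description`, `root_rnaseq`,
#'   `root_nano`, `shoot_rnaseq`, `shoot_nano`, `root_nano_code`,
#'   `shoot_nano_code`.
#' @export
nanostring_validation_panel <- function() {
  path <- system.file("extdata", "nanostring_validation_log2fc.tsv",
                      package = "ckreg", mustWork = TRUE)
  df <- read_tsv_manifest(path)
  parse_col <- function(x) suppressWarnings(as.numeric(x))
  out <- data.frame(gene_id = df$gene_id, description = df$description,
                    root_rnaseq = parse_col(df$root_rnaseq),
                    root_nano = parse_col(df$root_nano),
                    shoot_rnaseq = parse_col(df$shoot_rnaseq),
                    shoot_nano = parse_col(df$shoot_nano),
                    root_nano_code = ifelse(grepl("^nd$|^ND$", df$root_nano),
                                            df$root_nano, ""),
                    shoot_nano_code = ifelse(grepl("^nd$|^ND$", df$shoot_nano),
                                             df$shoot_nano, ""),
                    stringsAsFactors = FALSE)
  out
}
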