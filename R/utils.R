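#' @keywords internal
"_PACKAGE"

#' @importFrom stats ave cor lsfit p.adjust phyper rnorm rpois runif sd setNames
#' @importFrom graphics hist
#' @importFrom utils read.delim write.table packageVersion head
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
# All randomness in the package flows through this helper so results are pure
# functions of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483647L
}

rev_comp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write a TSV with a commented run-manifest header
#'
#' All pipeline outputs use this writer: `#`-prefixed `key=value` lines record
#' the parameters and seed of the run, followed by a standard header row.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param manifest named list of scalar parameter values recorded as comments.
#' @return `path`, invisibly.
#' @export
write_tsv_manifest <- function(df, path, manifest = list()) {
  manifest <- c(list(tool = paste0("ckreg ", as.character(packageVersion("ckreg")))),
                manifest)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(manifest)) {
    writeLines(sprintf("# %s=%s", k, as.character(manifest[[k]])), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_manifest()]
#'
#' @param path file path.
#' @return data frame; the parsed manifest is attached as attribute
#'   `"manifest"` (a named character vector).
#' @export
read_tsv_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  manifest <- character(0)
  if (length(hdr)) {
    kv <- sub("^#\\s*", "", lines[hdr])
    keys <- sub("=.*$", "", kv)
    manifest <- setNames(sub("^[^=]*=", "", kv), keys)
  }
  df <- read.delim(text = lines[setdiff(seq_along(lines), hdr)],
                   stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "manifest") <- manifest
  df
}
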