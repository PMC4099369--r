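#' Construct a genotype matrix
#'
#' Bundles an integer marker-code matrix with its ploidy and identifiers.
#' Diploid codes count copies of the reference allele (0, 1, 2); haploid
#' (or inbred-line) codes are indicators of the reference homozygote (0, 1).
#' Missing values are not permitted: incomplete individuals must be removed
#' before analysis.
#'
#' @param codes integer matrix, individuals in rows and markers in columns.
#' @param ploidy `"diploid"` or `"haploid"`.
#' @param sample_ids character vector of row identifiers; defaults to
#'   existing rownames or `ind1..indn`.
#' @param marker_ids character vector of column identifiers; defaults to
#'   existing colnames or `mk1..mkm`.
#' @return An object of class `"geno"`: a list with elements `codes`,
#'   `ploidy`, `sample_ids`, `marker_ids`.
#' @examples
#' g <- geno_matrix(matrix(c(0L, 1L, 2L, 1L), 2, 2), "diploid")
#' allele_freq(g)
#' @export
geno_matrix <- function(codes, ploidy = c("diploid", "haploid"),
                        sample_ids = NULL, marker_ids = NULL) {
  ploidy <- match.arg(ploidy)
  codes <- as.matrix(codes)
  if (nrow(codes) < 2L || ncol(codes) < 1L)
    stop("need at least 2 individuals and 1 marker")
  if (anyNA(codes))
    stop("missing genotype codes are not allowed; remove incomplete individuals first")
  storage.mode(codes) <- "integer"
  legal <- if (ploidy == "diploid") 0:2 else 0:1
  bad <- which(!(codes %in% legal))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(codes)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(codes)) + 1L
    stop(sprintf("illegal %s code %d at individual %d, marker %d",
                 ploidy, codes[bad[1L]], i, j))
  }
  if (is.null(sample_ids))
    sample_ids <- rownames(codes) %||% paste0("ind", seq_len(nrow(codes)))
  if (is.null(marker_ids))
    marker_ids <- colnames(codes) %||% paste0("mk", seq_len(ncol(codes)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (length(sample_ids) != nrow(codes) || length(marker_ids) != ncol(codes))
    stop("id lengths do not match matrix dimensions")
  dimnames(codes) <- list(sample_ids, marker_ids)
  structure(list(codes = codes, ploidy = ploidy,
                 sample_ids = as.character(sample_ids),
                 marker_ids = as.character(marker_ids)),
            class = "geno")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.geno <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d markers (%s)\n",
              nrow(x$codes), ncol(x$codes), x$ploidy))
  invisible(x)
}

#' @export
dim.geno <- function(x) dim(x$codes)

#' Reference-allele frequencies
#'
#' Per-marker estimated frequency of the reference allele: the mean code
#' divided by the ploidy (diploid markers carry two allele copies per
#' individual, haploid indicator codes one).
#'
#' @param g a [geno_matrix()] object.
#' @return Numeric vector of length `m`, named by marker.
#' @export
allele_freq <- function(g) {
  stopifnot(inherits(g, "geno"))
  k <- if (g$ploidy == "diploid") 2 else 1
  colMeans(g$codes) / k
}

#' Standardize genotype codes to unit variance
#'
#' Centers and scales each marker column by its estimated allele frequency:
#' diploid \eqn{w_{il} = (z_{il} - 2\hat p_l)/\sqrt{2\hat p_l(1-\hat p_l)}},
#' haploid \eqn{w_{il} = (z_{il} - \hat p_l)/\sqrt{\hat p_l(1-\hat p_l)}}.
#' Monomorphic markers (\eqn{\hat p_l \in \{0,1\}}) cannot be scaled and are
#' dropped with a warning.
#'
#' @param g a [geno_matrix()] object.
#' @return An object of class `"stdgeno"`: list with `w` (n x m' numeric
#'   matrix), `freqs` (retained allele frequencies), `ploidy`, `sample_ids`,
#'   `marker_ids`, and `n_dropped`.
#' @export
standardize_geno <- function(g) {
  stopifnot(inherits(g, "geno"))
  p <- allele_freq(g)
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all markers are monomorphic; nothing to standardize")
  if (!all(keep))
    warning(sprintf("dropping %d monomorphic marker(s)", sum(!keep)),
            call. = FALSE)
  z <- g$codes[, keep, drop = FALSE]
  p <- p[keep]
  k <- if (g$ploidy == "diploid") 2 else 1
  w <- sweep(z, 2L, k * p)
  w <- sweep(w, 2L, sqrt(k * p * (1 - p)), "/")
  structure(list(w = w, freqs = p, ploidy = g$ploidy,
                 sample_ids = g$sample_ids,
                 marker_ids = g$marker_ids[keep],
                 n_dropped = sum(!keep)),
            class = "stdgeno")
}

#' @export
print.stdgeno <- function(x, ...) {
  cat(sprintf("Standardized genotypes: %d x %d (%s, %d monomorphic dropped)\n",
              nrow(x$w), ncol(x$w), x$ploidy, x$n_dropped))
  invisible(x)
}
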