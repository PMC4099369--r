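# Delimited-text and GCTA binary interchange.
#
# Genotype TSV: header row of marker ids, first column the sample id,
# integer codes. Phenotype TSV: either GCTA-style FID IID value or
# two-column id value. GCTA binary GRM triple: <prefix>.grm.bin holds the
# lower triangle including the diagonal, row-major by individual, as
# 4-byte little-endian IEEE floats; <prefix>.grm.id lists FID IID;
# <prefix>.grm.N.bin (optional) the per-pair marker counts, same layout.

#' Read a genotype matrix from TSV
#'
#' @param path file path; @param ploidy `"diploid"` or `"haploid"`.
#' @return A [geno_matrix()].
#' @details Malformed input is rejected, never coerced: missing cells and
#'   illegal codes are reported with their sample/marker coordinates, and
#'   duplicate sample ids are an error. A diploid read whose codes never
#'   exceed 1 triggers a warning that the file may be haploid.
#' @export
read_genotypes <- function(path, ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "#")
  if (ncol(df) < 2L) stop("genotype file needs a sample-id column and markers")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  marker_ids <- colnames(df)[-1L]
  codes <- suppressWarnings(
    vapply(df[-1L], as.integer, integer(nrow(df))))
  if (!is.matrix(codes)) codes <- matrix(codes, nrow = nrow(df))
  raw <- as.matrix(df[-1L])
  bad <- which(is.na(codes) | raw == "" | is.na(raw))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(df)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(df)) + 1L
    stop(sprintf("missing or non-integer genotype at sample '%s', marker '%s'",
                 ids[i], marker_ids[j]))
  }
  legal <- if (ploidy == "diploid") 0:2 else 0:1
  bad <- which(!(codes %in% legal))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(df)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(df)) + 1L
    stop(sprintf("illegal %s code '%s' at sample '%s', marker '%s'",
                 ploidy, raw[bad[1L]], ids[i], marker_ids[j]))
  }
  if (ploidy == "diploid" && max(codes) <= 1L)
    warning("no code exceeds 1; file may be haploid data read as diploid",
            call. = FALSE)
  geno_matrix(codes, ploidy = ploidy, sample_ids = ids,
              marker_ids = marker_ids)
}

#' Write a genotype matrix to TSV
#' @param g a [geno_matrix()]; @param path output file.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "geno"))
  df <- data.frame(id = g$sample_ids, g$codes, check.names = FALSE)
  colnames(df) <- c("id", g$marker_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read phenotypes from TSV
#'
#' Accepts GCTA-style three-column `FID IID value` (no header) or
#' two-column `id value` files; whitespace- or tab-delimited.
#'
#' @param path file path; @param trait_name label attached as an attribute.
#' @return Named numeric vector (names are the individual ids).
#' @export
read_phenotypes <- function(path, trait_name = "trait") {
  df <- utils::read.table(path, header = FALSE, colClasses = "character",
                          comment.char = "#")
  if (!ncol(df) %in% 2:3)
    stop("phenotype file must have 2 (id value) or 3 (FID IID value) columns")
  ids <- df[[ncol(df) - 1L]]
  y <- suppressWarnings(as.numeric(df[[ncol(df)]]))
  if (anyNA(y)) {
    k <- which(is.na(y))[1L]
    stop(sprintf("non-numeric phenotype '%s' for individual '%s'",
                 df[[ncol(df)]][k], ids[k]))
  }
  if (anyDuplicated(ids)) stop("duplicate individual id(s) in phenotype file")
  names(y) <- ids
  attr(y, "trait_name") <- trait_name
  y
}

#' Write phenotypes to GCTA-style TSV (FID IID value)
#' @param y named numeric vector; @param path output file.
#' @export
write_phenotypes <- function(y, path) {
  ids <- names(y) %||% paste0("ind", seq_along(y))
  utils::write.table(data.frame(ids, ids, as.numeric(y)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# lower triangle incl. diagonal, row-major by individual (GCTA order)
gcta_vech <- function(theta) {
  n <- nrow(theta)
  unlist(lapply(seq_len(n), function(i) theta[i, seq_len(i)]),
         use.names = FALSE)
}

#' Write a GRM in GCTA binary format
#'
#' Writes `<prefix>.grm.bin` (4-byte little-endian floats of the lower
#' triangle including the diagonal, row-major by individual),
#' `<prefix>.grm.id` (FID and IID, both the sample id), and, when the
#' marker count is known, `<prefix>.grm.N.bin` with that count for every
#' pair.
#'
#' @param grm a `"grm"` object; @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_grm_gcta <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  v <- gcta_vech(grm$theta)
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(v), con, size = 4L, endian = "little")
  utils::write.table(data.frame(grm$sample_ids, grm$sample_ids),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.na(grm$n_markers)) {
    conN <- file(paste0(prefix, ".grm.N.bin"), "wb")
    writeBin(rep(as.numeric(grm$n_markers), length(v)), conN, size = 4L,
             endian = "little")
    close(conN)
  }
  invisible(prefix)
}

#' Read a GRM from GCTA binary format
#'
#' @param prefix path prefix of the `.grm.bin` / `.grm.id`
#'   (/ `.grm.N.bin`) triple.
#' @return A `"grm"` object with `source = "file"`.
#' @export
read_grm_gcta <- function(prefix) {
  idfile <- paste0(prefix, ".grm.id")
  binfile <- paste0(prefix, ".grm.bin")
  if (!file.exists(idfile)) stop("missing ", idfile)
  if (!file.exists(binfile)) stop("missing ", binfile)
  ids <- utils::read.table(idfile, header = FALSE,
                           colClasses = "character")[[2L]]
  n <- length(ids)
  npairs <- n * (n + 1) / 2
  expected <- 4 * npairs
  actual <- file.size(binfile)
  if (actual != expected)
    stop(sprintf("%s has %d bytes; expected %d (= 4 * %d pairs for %d ids)",
                 binfile, actual, expected, npairs, n))
  con <- file(binfile, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = npairs, size = 4L, endian = "little")
  theta <- matrix(0, n, n)
  k <- 0L
  for (i in seq_len(n)) {
    theta[i, seq_len(i)] <- v[(k + 1L):(k + i)]
    k <- k + i
  }
  theta <- theta + t(theta) - diag(diag(theta))
  nfile <- paste0(prefix, ".grm.N.bin")
  nm <- NA_integer_
  if (file.exists(nfile)) {
    if (file.size(nfile) != expected)
      stop(sprintf("%s has %d bytes; expected %d", nfile, file.size(nfile),
                   expected))
    conN <- file(nfile, "rb")
    counts <- readBin(conN, "numeric", n = npairs, size = 4L,
                      endian = "little")
    close(conN)
    nm <- as.integer(round(counts[1L]))
  }
  new_grm(theta, ids, source = "file", n_markers = nm)
}

#' Write a GRM as plain TSV (for inspection)
#' @param grm a `"grm"`; @param path output file.
#' @export
write_grm_tsv <- function(grm, path) {
  stopifnot(inherits(grm, "grm"))
  utils::write.table(data.frame(id = grm$sample_ids, grm$theta,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
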