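#' Construct a multilocus codominant genotype table
#'
#' The central data container of the package: an individuals-by-loci matrix of
#' unordered diploid allele pairs. Allele labels are positive integers
#' (fragment lengths under length-based encodings, or arbitrary categorical
#' codes). Missing genotypes are `NA` in both allele slots; half-missing
#' genotypes are rejected. Genotypes are stored order-normalised so that
#' `(a, b)` and `(b, a)` are the same genotype.
#'
#' @param ids character vector of unique individual labels.
#' @param loci character vector of unique locus names.
#' @param a1,a2 integer matrices (`length(ids)` x `length(loci)`) holding the
#'   two alleles of every genotype; `NA` in both marks a missing genotype.
#' @return An object of class `genotype_table` with elements `ids`, `loci`,
#'   `a1`, `a2` (allele matrices with `a1 <= a2` elementwise).
#' @examples
#' gt <- genotype_table(c("A", "B"), "L1",
#'                      a1 = matrix(c(158L, 158L), 2, 1),
#'                      a2 = matrix(c(158L, 162L), 2, 1))
#' gt
#' @export
genotype_table <- function(ids, loci, a1, a2) {
  ids <- as.character(ids)
  loci <- as.character(loci)
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  if (anyDuplicated(ids))
    stop("duplicate individual id: ", ids[duplicated(ids)][1L])
  if (anyDuplicated(loci))
    stop("duplicate locus name: ", loci[duplicated(loci)][1L])
  if (!all(dim(a1) == c(length(ids), length(loci))) ||
      !all(dim(a2) == c(length(ids), length(loci))))
    stop("allele matrices must be ", length(ids), " x ", length(loci))
  if (!identical(is.na(a1), is.na(a2))) {
    bad <- which(is.na(a1) != is.na(a2), arr.ind = TRUE)[1L, ]
    stop("half-missing genotype for individual '", ids[bad[1L]],
         "' at locus '", loci[bad[2L]],
         "': both alleles must be present or both missing")
  }
  if (any(a1 <= 0L, na.rm = TRUE) || any(a2 <= 0L, na.rm = TRUE))
    stop("allele labels must be positive integers")
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  dimnames(lo) <- dimnames(hi) <- list(ids, loci)
  structure(list(ids = ids, loci = loci, a1 = lo, a2 = hi),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$ids), "individuals x",
      length(x$loci), "loci\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
`[.genotype_table` <- function(x, i, j) {
  if (missing(i)) i <- seq_along(x$ids)
  if (missing(j)) j <- seq_along(x$loci)
  genotype_table(x$ids[i], x$loci[j],
                 x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE])
}

#' Fraction of missing genotypes per locus or per individual
#'
#' @param x a [genotype_table()].
#' @param by `"locus"` or `"individual"`.
#' @return Named numeric vector of missing fractions in `[0, 1]`.
#' @export
missing_fraction <- function(x, by = c("locus", "individual")) {
  by <- match.arg(by)
  miss <- is.na(x$a1)
  if (by == "locus") colMeans(miss) else rowMeans(miss)
}

#' Read and write genotype tables
#'
#' Two plain-CSV layouts are supported. The native layout has a header
#' `individual,<locus>_1,<locus>_2,...` with one row per individual. The
#' GenAlEx-style layout has two header rows (first: number of loci and of
#' individuals; second: the individual column name followed by each locus
#' name over the first of its two allele columns) and the same one-row-per-
#' individual body. In both, the missing-data code is `0` in each allele
#' column (the GenAlEx convention).
#'
#' @param path file path.
#' @param format `"native"` or `"genalex"`.
#' @return `read_genotypes` returns a [genotype_table()];
#'   `write_genotypes` invisibly returns `path`.
#' @export
read_genotypes <- function(path, format = c("native", "genalex")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         native = .read_native(path),
         genalex = .read_genalex(path))
}

#' @rdname read_genotypes
#' @param x a [genotype_table()] to write.
#' @export
write_genotypes <- function(x, path, format = c("native", "genalex")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "genotype_table"))
  a1 <- x$a1; a2 <- x$a2
  a1[is.na(a1)] <- 0L
  a2[is.na(a2)] <- 0L
  body <- matrix(0L, length(x$ids), 2L * length(x$loci))
  body[, seq(1L, ncol(body), by = 2L)] <- a1
  body[, seq(2L, ncol(body), by = 2L)] <- a2
  rows <- apply(cbind(x$ids, body), 1L, paste, collapse = ",")
  header <- switch(format,
    native = paste(c("individual",
                     as.vector(rbind(paste0(x$loci, "_1"),
                                     paste0(x$loci, "_2")))),
                   collapse = ","),
    genalex = paste(
      paste(length(x$loci), length(x$ids), sep = ","),
      paste(c("individual",
              as.vector(rbind(x$loci, rep("", length(x$loci))))),
            collapse = ","),
      sep = "\n"))
  writeLines(c(header, rows), path)
  invisible(path)
}

.parse_allele_cell <- function(v, what) {
  out <- suppressWarnings(as.integer(v))
  if (anyNA(out) || any(out < 0L))
    stop("non-integer or negative allele value in ", what)
  out
}

.body_to_table <- function(ids, loci, cells, path) {
  n <- length(ids); L <- length(loci)
  if (anyDuplicated(ids))
    stop("duplicate individual id '", ids[duplicated(ids)][1L],
         "' in ", path)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    v1 <- .parse_allele_cell(cells[, 2L * l - 1L],
                             paste0("locus '", loci[l], "' of ", path))
    v2 <- .parse_allele_cell(cells[, 2L * l],
                             paste0("locus '", loci[l], "' of ", path))
    half <- xor(v1 == 0L, v2 == 0L)
    if (any(half))
      stop("half-missing genotype (single 0) for individual '",
           ids[which(half)[1L]], "' at locus '", loci[l], "' in ", path)
    keep <- v1 != 0L
    a1[keep, l] <- v1[keep]
    a2[keep, l] <- v2[keep]
  }
  genotype_table(ids, loci, a1, a2)
}

.read_native <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("no data rows in ", path)
  fields <- strsplit(lines, ",", fixed = TRUE)
  header <- fields[[1L]]
  if (tolower(header[1L]) != "individual")
    stop("unknown format in ", path,
         ": first header column must be 'individual'")
  acols <- header[-1L]
  if (length(acols) == 0L || length(acols) %% 2L != 0L)
    stop("malformed header in ", path,
         ": odd number of allele columns (", length(acols), ")")
  l1 <- acols[seq(1L, length(acols), by = 2L)]
  l2 <- acols[seq(2L, length(acols), by = 2L)]
  if (!all(grepl("_1$", l1)) || !all(grepl("_2$", l2)) ||
      !all(sub("_1$", "", l1) == sub("_2$", "", l2)))
    stop("malformed header in ", path,
         ": allele columns must come in <locus>_1,<locus>_2 pairs")
  loci <- sub("_1$", "", l1)
  body <- fields[-1L]
  nf <- lengths(body)
  if (any(nf != length(header)))
    stop("malformed row ", which(nf != length(header))[1L] + 1L, " in ",
         path, ": expected ", length(header), " fields")
  cells <- do.call(rbind, body)
  .body_to_table(cells[, 1L], loci, cells[, -1L, drop = FALSE], path)
}

.read_genalex <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("no data rows in ", path)
  fields <- strsplit(lines, ",", fixed = TRUE)
  counts <- suppressWarnings(as.integer(fields[[1L]]))
  if (length(counts) < 2L || anyNA(counts[1:2]))
    stop("malformed GenAlEx header in ", path,
         ": first row must give locus and individual counts")
  nloci <- counts[1L]; nind <- counts[2L]
  header <- fields[[2L]]
  loci_pos <- seq(2L, by = 2L, length.out = nloci)
  if (length(header) < max(loci_pos))
    stop("malformed GenAlEx header in ", path,
         ": expected ", nloci, " loci in second row")
  loci <- header[loci_pos]
  body <- fields[-(1:2)]
  body <- body[vapply(body, function(f) any(nzchar(f)), logical(1L))]
  if (length(body) != nind)
    stop("GenAlEx file ", path, " declares ", nind,
         " individuals but has ", length(body), " data rows")
  nf <- lengths(body)
  need <- 1L + 2L * nloci
  if (any(nf < need))
    stop("malformed row ", which(nf < need)[1L] + 2L, " in ", path,
         ": expected ", need, " fields")
  cells <- do.call(rbind, lapply(body, function(f) f[seq_len(need)]))
  .body_to_table(cells[, 1L], loci, cells[, -1L, drop = FALSE], path)
}

#' Filter loci and individuals by missing-data fraction
#'
#' Drops loci whose missing fraction exceeds `max_missing`, then recomputes
#' individual missingness over the retained loci and drops individuals still
#' above the threshold (or the reverse order when `drop_loci_first = FALSE`).
#' The locus-first order means an individual whose gaps are concentrated in
#' dropped loci is retained.
#'
#' @param x a [genotype_table()].
#' @param max_missing maximum tolerated missing fraction, in `[0, 1)`.
#' @param drop_loci_first filter loci before individuals (default).
#' @return A list with `table` (the filtered [genotype_table()]) and
#'   `report`, a data frame of removed loci/individuals with their missing
#'   fractions at removal time.
#' @export
filter_missing <- function(x, max_missing = 0.10, drop_loci_first = TRUE) {
  stopifnot(inherits(x, "genotype_table"))
  if (!is.numeric(max_missing) || max_missing < 0 || max_missing >= 1)
    stop("max_missing must be in [0, 1)")
  report <- data.frame(type = character(), id = character(),
                       missing_fraction = numeric(),
                       stringsAsFactors = FALSE)
  drop_pass <- function(x, by) {
    mf <- missing_fraction(x, by)
    bad <- mf > max_missing
    if (any(bad)) {
      report <<- rbind(report, data.frame(
        type = if (by == "locus") "locus" else "individual",
        id = names(mf)[bad], missing_fraction = unname(mf[bad]),
        stringsAsFactors = FALSE))
      if (by == "locus") {
        if (all(bad)) stop("all loci exceed the missing-data threshold")
        x <- x[, !bad]
      } else {
        if (all(bad)) stop("all individuals exceed the missing-data threshold")
        x <- x[!bad, ]
      }
    }
    x
  }
  order_by <- if (drop_loci_first) c("locus", "individual")
              else c("individual", "locus")
  for (by in order_by) x <- drop_pass(x, by)
  list(table = x, report = report)
}

#' Allele relative frequencies at one locus
#'
#' Plain sample-proportion estimator over non-missing genotypes:
#' `freq(allele) = count(allele) / (2 * n_genotyped)`. These frequencies feed
#' the heterozygosity, exclusion, identity and relatedness-likelihood
#' computations.
#'
#' @param x a [genotype_table()].
#' @param locus locus name.
#' @return An object of class `locus_frequencies`: a list with `locus`,
#'   `alleles` (sorted integer labels), `freqs` (summing to 1) and
#'   `n_genotyped`.
#' @export
allele_frequencies <- function(x, locus) {
  stopifnot(inherits(x, "genotype_table"))
  if (!locus %in% x$loci) stop("locus '", locus, "' not in table")
  v1 <- x$a1[, locus]
  v2 <- x$a2[, locus]
  keep <- !is.na(v1)
  if (!any(keep))
    stop("locus '", locus, "' has no genotyped individuals")
  tab <- table(c(v1[keep], v2[keep]))
  structure(list(locus = locus,
                 alleles = as.integer(names(tab)),
                 freqs = as.numeric(tab) / (2 * sum(keep)),
                 n_genotyped = sum(keep)),
            class = "locus_frequencies")
}

#' @export
print.locus_frequencies <- function(x, ...) {
  cat("locus", x$locus, "-", length(x$alleles), "alleles, n =",
      x$n_genotyped, "\n")
  print(stats::setNames(round(x$freqs, 4), x$alleles))
  invisible(x)
}

#' Allele frequencies at every locus of a table
#'
#' @param x a [genotype_table()].
#' @return Named list of [allele_frequencies()] results, one per locus.
#' @export
loci_frequencies <- function(x) {
  stats::setNames(lapply(x$loci, function(l) allele_frequencies(x, l)),
                  x$loci)
}

# Coerce locus_frequencies / named numeric to a plain frequency vector.
.as_p <- function(freqs) {
  if (inherits(freqs, "locus_frequencies")) return(freqs$freqs)
  if (is.numeric(freqs)) {
    if (any(freqs < 0)) stop("negative allele frequency")
    s <- sum(freqs)
    if (abs(s - 1) > 1e-8) stop("allele frequencies must sum to 1")
    return(as.numeric(freqs))
  }
  stop("expected a locus_frequencies object or a numeric frequency vector")
}
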