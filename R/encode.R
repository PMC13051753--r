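#' Allele sequences with repeat annotations
#'
#' Container pairing per-allele nucleotide sequences with their annotated
#' repeat intervals. `records` holds one row per sequenced allele copy with
#' columns `name` (record id `individual|locus|copy`, copy in `{1, 2}`),
#' `individual`, `locus`, `copy` and `seq`. `annotations` holds one row per
#' annotated repeat with columns `name` (matching a record id), `start`,
#' `end` (0-based half-open within the record's sequence), `motif` and
#' `target` (logical; exactly one target repeat per record).
#'
#' @param records data frame as described above (the `individual`, `locus`
#'   and `copy` columns are derived from `name` when absent).
#' @param annotations data frame as described above.
#' @return An object of class `allele_sequences`.
#' @export
allele_sequences <- function(records, annotations) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (!all(c("name", "seq") %in% names(records)))
    stop("records must have columns 'name' and 'seq'")
  parts <- strsplit(records$name, "|", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("record ids must be '<individual>|<locus>|<copy>'; offending id: ",
         records$name[lengths(parts) != 3L][1L])
  records$individual <- vapply(parts, `[`, "", 1L)
  records$locus <- vapply(parts, `[`, "", 2L)
  records$copy <- as.integer(vapply(parts, `[`, "", 3L))
  if (!all(records$copy %in% 1:2))
    stop("allele copy index must be 1 or 2")
  if (!all(c("name", "start", "end", "motif", "target") %in%
           names(annotations)))
    stop("annotations must have columns name, start, end, motif, target")
  annotations$target <- as.logical(annotations$target)
  ntarget <- vapply(records$name, function(id)
    sum(annotations$target[annotations$name == id]), integer(1L))
  if (any(ntarget != 1L))
    stop("sequence without a single target-repeat annotation: ",
         records$name[ntarget != 1L][1L])
  lens <- nchar(records$seq)[match(annotations$name, records$name)]
  if (anyNA(lens))
    stop("annotation for unknown record: ",
         annotations$name[is.na(lens)][1L])
  if (any(annotations$start < 0L) || any(annotations$end > lens) ||
      any(annotations$end <= annotations$start))
    stop("annotation interval outside its sequence")
  structure(list(records = records, annotations = annotations),
            class = "allele_sequences")
}

#' Read allele sequences from FASTA plus a repeat-annotation sidecar
#'
#' FASTA record ids must follow `<individual>|<locus>|<copy>` with copy 1 or
#' 2 (a single record for an individual/locus pair is read as a homozygote
#' by [encode_alleles()]). The sidecar is a BED-like TSV with header
#' `name  start  end  motif  target` giving 0-based half-open repeat
#' intervals on each record, the `target` column (0/1) marking the target
#' microsatellite.
#'
#' @param fasta path to the FASTA file.
#' @param annotations path to the annotation TSV.
#' @return An [allele_sequences()] object.
#' @export
read_allele_sequences <- function(fasta, annotations) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  records <- data.frame(name = names(seqs),
                        seq = as.character(seqs),
                        stringsAsFactors = FALSE)
  ann <- utils::read.delim(annotations, stringsAsFactors = FALSE)
  allele_sequences(records, ann)
}

#' Encode allele sequences into a genotype table
#'
#' Four encoding schemes turn sequenced alleles into integer allele labels:
#' * `FullLength` - total sequence length (flanks + repeat), the encoding
#'   equivalent to classical fragment-length genotyping;
#' * `RepeatFocused` - length of the target microsatellite only;
#' * `SSRs` - the tuple of all annotated repeat lengths, mapped to one
#'   categorical code per distinct tuple;
#' * `CAT` - one categorical code per distinct full sequence, so repeats,
#'   SNPs and indels all distinguish alleles.
#'
#' Categorical codes are assigned per locus in first-appearance order of the
#' input records, so the encoding is deterministic and file-representable.
#' An individual with a single record at a locus is a homozygote; with none,
#' missing.
#'
#' @param seqs an [allele_sequences()] object.
#' @param scheme one of `"FullLength"`, `"RepeatFocused"`, `"SSRs"`, `"CAT"`.
#' @return A [genotype_table()].
#' @export
encode_alleles <- function(seqs,
                           scheme = c("FullLength", "RepeatFocused",
                                      "SSRs", "CAT")) {
  stopifnot(inherits(seqs, "allele_sequences"))
  scheme <- match.arg(scheme)
  rec <- seqs$records
  ann <- seqs$annotations

  key_of <- function(name, seq) {
    a <- ann[ann$name == name, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    switch(scheme,
           FullLength = nchar(seq),
           RepeatFocused = {
             t <- a[a$target, , drop = FALSE]
             t$end - t$start
           },
           SSRs = paste(a$end - a$start, collapse = ","),
           CAT = seq)
  }
  keys <- mapply(key_of, rec$name, rec$seq)

  labels <- integer(nrow(rec))
  if (scheme %in% c("FullLength", "RepeatFocused")) {
    labels <- as.integer(keys)
  } else {
    for (l in unique(rec$locus)) {
      sel <- rec$locus == l
      labels[sel] <- match(keys[sel], unique(keys[sel]))
    }
  }

  ids <- unique(rec$individual)
  loci <- unique(rec$locus)
  a1 <- matrix(NA_integer_, length(ids), length(loci))
  a2 <- matrix(NA_integer_, length(ids), length(loci))
  for (r in split(seq_len(nrow(rec)),
                  paste(rec$individual, rec$locus, sep = "\r"))) {
    if (length(r) > 2L)
      stop("more than two allele records for individual '",
           rec$individual[r[1L]], "' at locus '", rec$locus[r[1L]], "'")
    i <- match(rec$individual[r[1L]], ids)
    j <- match(rec$locus[r[1L]], loci)
    lab <- labels[r][order(rec$copy[r])]
    a1[i, j] <- lab[1L]
    a2[i, j] <- lab[length(lab)]
  }
  genotype_table(ids, loci, a1, a2)
}
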