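# Chain records and the fixed-width partitioned alignment.

#' Create a validated collagen chain record
#'
#' A chain record holds one alpha-chain amino-acid sequence for one
#' taxon.  Helical-domain records are validated against the fixed chain
#' widths of collagen (I): alpha1 = 1058, alpha2 = 1041, alpha3 = 1062
#' sites (ungapped), unless `relaxed = TRUE` (used for classifier inputs
#' such as single tryptic peptides).
#'
#' @param taxon species identifier (non-empty string).
#' @param chain one of `"alpha1"`, `"alpha2"`, `"alpha3"`, `"unknown"`.
#' @param sequence amino-acid string over the 20-letter alphabet plus
#'   `-` (gap) and `X` (unknown residue).
#' @param isoform optional isoform tag (e.g. `"A"`/`"B"` for tetraploid
#'   gene copies); `NA` when the taxon has a single copy.
#' @param region `"helical"` (triple-helical domain only) or
#'   `"procollagen"` (full precursor including signal peptide,
#'   propeptides and telopeptides).
#' @param source_id free-text provenance (accession or note).
#' @param relaxed if `TRUE`, skip the fixed-length check.
#' @return an object of class `"chain_record"`.
#' @examples
#' r <- chain_record("Danio_rerio", "alpha1", "GGPGVVGPKGATGEPGR",
#'                   relaxed = TRUE)
#' r$taxon
#' @export
chain_record <- function(taxon, chain, sequence, isoform = NA_character_,
                         region = c("helical", "procollagen"),
                         source_id = "", relaxed = FALSE) {
  region <- match.arg(region)
  if (!is.character(taxon) || length(taxon) != 1L || !nzchar(taxon))
    stop("'taxon' must be a non-empty string")
  chain <- match.arg(chain, c("alpha1", "alpha2", "alpha3", "unknown"))
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("'sequence' must be a non-empty string")
  sequence <- toupper(sequence)
  bad <- first_bad_char(sequence, c(AA20, AA_EXTRA))
  if (bad > 0L)
    stop(sprintf(
      "illegal character '%s' at position %d in record for taxon '%s'",
      substr(sequence, bad, bad), bad, taxon))
  if (!relaxed && region == "helical" && chain %in% CHAINS) {
    ungapped <- nchar(gsub("-", "", sequence, fixed = TRUE))
    want <- CHAIN_LENGTHS[[chain]]
    if (ungapped != want)
      stop(sprintf(
        "helical %s record for '%s' has ungapped length %d, expected %d (use relaxed = TRUE for fragments)",
        chain, taxon, ungapped, want))
  }
  structure(
    list(taxon = taxon, chain = chain, isoform = as.character(isoform),
         sequence = sequence, region = region, source_id = source_id),
    class = "chain_record")
}

#' @export
print.chain_record <- function(x, ...) {
  iso <- if (is.na(x$isoform)) "" else paste0(" isoform ", x$isoform)
  cat(sprintf("<chain_record> %s %s%s (%s, %d aa)\n",
              x$taxon, x$chain, iso, x$region, nchar(x$sequence)))
  invisible(x)
}

#' Read collagen chain records from a FASTA file
#'
#' Headers use a pipe-delimited grammar
#' `>taxon|chain|isoform|region optional free text`, where `chain` is
#' one of `alpha1`/`alpha2`/`alpha3`/`unknown`, `isoform` is a short tag
#' (empty for none) and `region` is `helical` or `procollagen`.  Missing
#' trailing fields fall back to `defaults`; text after the first space
#' becomes `source_id`.
#'
#' @param path FASTA file of amino-acid sequences.
#' @param defaults named list of fallbacks for header fields
#'   (`chain`, `isoform`, `region`).
#' @param relaxed passed to [chain_record()]; allows fragment lengths.
#' @return list of [chain_record()] objects.
#' @export
read_chain_fasta <- function(path,
                             defaults = list(chain = "unknown",
                                             isoform = NA_character_,
                                             region = "helical"),
                             relaxed = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank))
    stop("malformed FASTA (empty file): ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop(sprintf("malformed FASTA at line %d: expected '>' header first",
                 nonblank[1]))
  seqs <- Biostrings::readBStringSet(path)
  if (!length(seqs)) stop("malformed FASTA (no records): ", path)
  headers <- names(seqs)
  lapply(seq_along(seqs), function(i) {
    h <- headers[i]
    main <- sub("\\s.*$", "", h)
    src <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
    tok <- strsplit(main, "|", fixed = TRUE)[[1]]
    pick <- function(k, fb) {
      if (length(tok) >= k && nzchar(tok[k])) tok[k] else fb
    }
    chain_records_from_fields(
      taxon = tok[1],
      chain = pick(2L, defaults$chain %||% "unknown"),
      isoform = pick(3L, defaults$isoform %||% NA_character_),
      region = pick(4L, defaults$region %||% "helical"),
      sequence = as.character(seqs[[i]]),
      source_id = src, relaxed = relaxed)
  })
}

chain_records_from_fields <- function(taxon, chain, isoform, region,
                                      sequence, source_id, relaxed) {
  chain_record(taxon = taxon, chain = chain, sequence = sequence,
               isoform = isoform, region = region,
               source_id = source_id, relaxed = relaxed)
}

#' Write chain records to FASTA
#'
#' Inverse of [read_chain_fasta()]: headers follow the
#' `taxon|chain|isoform|region source_id` grammar.
#'
#' @param records list of [chain_record()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_chain_fasta <- function(records, path) {
  stopifnot(length(records) > 0)
  hdr <- vapply(records, function(r) {
    iso <- if (is.na(r$isoform)) "" else r$isoform
    h <- paste(r$taxon, r$chain, iso, r$region, sep = "|")
    if (nzchar(r$source_id)) h <- paste(h, r$source_id)
    h
  }, character(1))
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, character(1),
                                        "sequence"))
  names(seqs) <- hdr
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Fixed partition map of the concatenated alignment
#'
#' @return data.frame with columns `chain`, `start`, `end`
#'   (1-based, closed intervals): alpha1 1--1058, alpha2 1059--2099,
#'   alpha3 2100--3161.
#' @export
chain_partitions <- function() {
  ends <- cumsum(CHAIN_LENGTHS)
  starts <- c(1L, head(ends, -1L) + 1L)
  data.frame(chain = CHAINS, start = unname(starts), end = unname(ends),
             stringsAsFactors = FALSE)
}

#' Concatenate chain records into a partitioned alignment
#'
#' Builds the taxa x 3161 matrix with column order alpha1 (1--1058),
#' alpha2 (1059--2099), alpha3 (2100--3161).  A taxon must contribute
#' both an alpha1 and an alpha2 chain to be included; taxa failing this
#' are dropped with a warning.  A missing alpha3 chain is filled with
#' `-`, treating absence as biological rather than a data gap.
#'
#' @param records list of [chain_record()] objects (helical region,
#'   full-length).
#' @param taxa optional ordered character vector restricting and
#'   ordering the output rows; default: all eligible taxa, sorted.
#' @param isoform_policy for taxa carrying tetraploid A/B isoform pairs,
#'   which copy enters the alignment (default `"A"`); a record with no
#'   isoform tag always qualifies.
#' @return object of class `"concat_alignment"`: list with `taxa`,
#'   `matrix` (character matrix of residues, rownames = taxa) and
#'   `partitions` (see [chain_partitions()]).
#' @export
concatenate_chains <- function(records, taxa = NULL, isoform_policy = "A") {
  stopifnot(length(records) > 0)
  ok <- vapply(records, inherits, logical(1), "chain_record")
  if (!all(ok)) stop("all elements must be chain_record objects")
  reg <- vapply(records, `[[`, character(1), "region")
  if (any(reg != "helical"))
    stop("only helical-region records can be concatenated")

  tab <- data.frame(
    i = seq_along(records),
    taxon = vapply(records, `[[`, character(1), "taxon"),
    chain = vapply(records, `[[`, character(1), "chain"),
    isoform = vapply(records, `[[`, character(1), "isoform"),
    stringsAsFactors = FALSE)
  if (any(tab$chain == "unknown"))
    stop("records with chain 'unknown' cannot be concatenated; classify first")
  key <- paste(tab$taxon, tab$chain, tab$isoform, sep = "\r")
  if (anyDuplicated(key)) {
    d <- tab[duplicated(key), , drop = FALSE]
    stop(sprintf("duplicate record for taxon '%s', chain %s, isoform %s",
                 d$taxon[1], d$chain[1], d$isoform[1]))
  }

  pick_record <- function(taxon, chain) {
    sub <- tab[tab$taxon == taxon & tab$chain == chain, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    if (nrow(sub) == 1L) return(records[[sub$i]])
    hit <- sub[!is.na(sub$isoform) & sub$isoform == isoform_policy, ,
               drop = FALSE]
    if (nrow(hit) == 1L) return(records[[hit$i]])
    hit <- sub[is.na(sub$isoform), , drop = FALSE]
    if (nrow(hit) == 1L) return(records[[hit$i]])
    stop(sprintf(
      "cannot choose an isoform for taxon '%s' chain %s under policy '%s'",
      taxon, chain, isoform_policy))
  }

  all_taxa <- if (is.null(taxa)) sort(unique(tab$taxon)) else taxa
  parts <- chain_partitions()
  rows <- list()
  for (tx in all_taxa) {
    r1 <- pick_record(tx, "alpha1")
    r2 <- pick_record(tx, "alpha2")
    if (is.null(r1) || is.null(r2)) {
      warning(sprintf(
        "taxon '%s' excluded: alpha1 and alpha2 chains are both required",
        tx), call. = FALSE)
      next
    }
    r3 <- pick_record(tx, "alpha3")
    chunk <- character(0)
    for (k in seq_len(nrow(parts))) {
      width <- parts$end[k] - parts$start[k] + 1L
      rec <- switch(parts$chain[k], alpha1 = r1, alpha2 = r2, alpha3 = r3)
      if (is.null(rec)) {
        chunk <- c(chunk, rep("-", width))
      } else {
        ch <- seq_chars(rec$sequence)
        if (length(ch) != width)
          stop(sprintf(
            "taxon '%s' %s sequence has %d columns, partition width is %d",
            tx, parts$chain[k], length(ch), width))
        chunk <- c(chunk, ch)
      }
    }
    rows[[tx]] <- chunk
  }
  if (!length(rows)) stop("no taxon satisfies the alpha1 + alpha2 requirement")
  m <- do.call(rbind, rows)
  new_concat_alignment(m, parts)
}

#' Construct a partitioned alignment from a character matrix
#'
#' Lower-level constructor used when the alignment does not come from
#' [concatenate_chains()] -- e.g. simulated partitions of non-canonical
#' lengths.  Partition intervals must tile the columns contiguously
#' from column 1.
#'
#' @param matrix character matrix of residues with taxon rownames.
#' @param partitions data.frame with `chain`, `start`, `end` (1-based
#'   closed intervals); default: the canonical chain partitions.
#' @return a `"concat_alignment"`.
#' @export
concat_alignment <- function(matrix, partitions = chain_partitions()) {
  new_concat_alignment(matrix, partitions)
}

# constructor enforcing the column-arithmetic invariants
new_concat_alignment <- function(m, partitions = chain_partitions()) {
  stopifnot(is.matrix(m), is.character(m), !is.null(rownames(m)))
  total <- sum(partitions$end - partitions$start + 1L)
  if (ncol(m) != total)
    stop(sprintf("alignment has %d columns; partitions require %d",
                 ncol(m), total))
  if (any(partitions$start > partitions$end))
    stop("invalid partition intervals")
  if (!identical(partitions$start[-1L], head(partitions$end, -1L) + 1L) ||
      partitions$start[1L] != 1L)
    stop("partitions must tile the alignment contiguously from column 1")
  structure(list(taxa = rownames(m), matrix = m, partitions = partitions),
            class = "concat_alignment")
}

#' @export
print.concat_alignment <- function(x, ...) {
  cat(sprintf("<concat_alignment> %d taxa x %d columns\n",
              nrow(x$matrix), ncol(x$matrix)))
  p <- x$partitions
  for (k in seq_len(nrow(p)))
    cat(sprintf("  %s: columns %d-%d (%d sites)\n", p$chain[k], p$start[k],
                p$end[k], p$end[k] - p$start[k] + 1L))
  invisible(x)
}

#' Extract one chain partition from a concatenated alignment
#'
#' @param aln a `"concat_alignment"`.
#' @param chain `"alpha1"`, `"alpha2"` or `"alpha3"`.
#' @return character matrix of the partition's columns.
#' @export
alignment_partition <- function(aln, chain) {
  stopifnot(inherits(aln, "concat_alignment"))
  p <- aln$partitions[aln$partitions$chain == chain, , drop = FALSE]
  if (!nrow(p)) stop("no partition named '", chain, "'")
  aln$matrix[, p$start:p$end, drop = FALSE]
}

#' Write a partitioned alignment to disk
#'
#' FASTA and PHYLIP outputs carry the partition map in a TSV sidecar
#' (`<path>.partitions.tsv`); NEXUS output embeds it as a
#' `SETS` block with one `CHARSET` per chain.  All coordinates are
#' 1-based closed intervals.
#'
#' @param aln a `"concat_alignment"`.
#' @param path output file path.
#' @param format `"fasta"`, `"nexus"` or `"phylip"` (relaxed names).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "nexus", "phylip")) {
  format <- match.arg(format)
  stopifnot(inherits(aln, "concat_alignment"))
  if (nrow(aln$matrix) == 0L) stop("refusing to write an empty alignment")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write to missing directory: ", dir)
  m <- aln$matrix
  seq_strings <- apply(m, 1L, paste, collapse = "")
  if (format == "fasta") {
    ss <- Biostrings::BStringSet(seq_strings)
    names(ss) <- rownames(m)
    Biostrings::writeXStringSet(ss, path, width = 80L)
    write_partition_sidecar(aln$partitions, paste0(path, ".partitions.tsv"))
  } else if (format == "phylip") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
    writeLines(sprintf("%s  %s", rownames(m), seq_strings), con)
    write_partition_sidecar(aln$partitions, paste0(path, ".partitions.tsv"))
  } else {
    ape::write.nexus.data(
      stats::setNames(lapply(seq_len(nrow(m)), function(i) m[i, ]),
                      rownames(m)),
      path, format = "protein", interleaved = FALSE)
    p <- aln$partitions
    sets <- c("BEGIN SETS;",
              sprintf("  CHARSET %s = %d-%d;", p$chain, p$start, p$end),
              "END;")
    cat(sets, file = path, sep = "\n", append = TRUE)
  }
  invisible(path)
}

write_partition_sidecar <- function(partitions, path) {
  utils::write.table(partitions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a partitioned alignment written by [write_alignment()]
#'
#' @param path alignment file.
#' @param format `"fasta"`, `"nexus"` or `"phylip"`.
#' @return a `"concat_alignment"`.
#' @export
read_alignment <- function(path, format = c("fasta", "nexus", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    m <- do.call(rbind, lapply(as.character(ss), seq_chars))
    rownames(m) <- sub("\\s.*$", "", names(ss))
    parts <- read_partition_sidecar(paste0(path, ".partitions.tsv"))
  } else if (format == "phylip") {
    lines <- readLines(path, warn = FALSE)
    hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
    body <- lines[-1][nzchar(trimws(lines[-1]))]
    if (length(body) != hdr[1]) stop("PHYLIP taxon count mismatch in ", path)
    nm <- sub("\\s.*$", "", body)
    sq <- sub("^\\S+\\s+", "", body)
    m <- do.call(rbind, lapply(sq, seq_chars))
    rownames(m) <- nm
    parts <- read_partition_sidecar(paste0(path, ".partitions.tsv"))
  } else {
    x <- ape::read.nexus.data(path)
    m <- do.call(rbind, lapply(x, toupper))
    rownames(m) <- names(x)
    parts <- read_nexus_charsets(path)
  }
  new_concat_alignment(m, parts)
}

read_partition_sidecar <- function(path) {
  if (!file.exists(path)) return(chain_partitions())
  p <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  p[, c("chain", "start", "end")]
}

read_nexus_charsets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hits <- regmatches(lines,
                     regexec("CHARSET\\s+(\\S+)\\s*=\\s*(\\d+)-(\\d+);",
                             lines, ignore.case = TRUE))
  hits <- Filter(length, hits)
  if (!length(hits)) return(chain_partitions())
  data.frame(
    chain = vapply(hits, `[`, character(1), 2),
    start = as.integer(vapply(hits, `[`, character(1), 3)),
    end = as.integer(vapply(hits, `[`, character(1), 4)),
    stringsAsFactors = FALSE)
}
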