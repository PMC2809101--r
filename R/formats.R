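#' Read a FASTA file of region sequences
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file into a tidy
#' sequence table.  Sequences are uppercased and RNA input is normalized to
#' the DNA alphabet (`U` becomes `T`); `N` is preserved.  Characters outside
#' `{A,C,G,T,N}` after normalization are rejected with the offending line
#' number.
#'
#' @param path Path to a FASTA file.
#' @param region Region label attached to every record, one of
#'   `"utr3"`, `"utr5"`, `"cds"`, `"cdna"`, `"promoter"`.
#' @return A tibble with columns `seq_id`, `region` and `sequence`, one row
#'   per FASTA record, in file order.
#' @seealso [collapse_isoforms()], [write_fasta()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "acgu", ">g2", "TTTT"), tf)
#' read_fasta(tf, "utr3")
read_fasta <- function(path, region = c("utr3", "utr5", "cds", "cdna",
                                        "promoter")) {
  region <- match.arg(region)
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) {
    return(tibble::tibble(seq_id = character(), region = character(),
                          sequence = character()))
  }
  is_header <- startsWith(lines, ">")
  nonblank <- nzchar(trimws(lines))
  if (any(nonblank) && !is_header[which(nonblank)[1]]) {
    abort(sprintf("malformed FASTA: line %d precedes any '>' header",
                  which(nonblank)[1]))
  }
  # validate sequence lines so errors can name the line
  seq_lines <- which(!is_header & nonblank)
  bad <- seq_lines[grepl("[^ACGTNacgtnUu]", lines[seq_lines])]
  if (length(bad) > 0) {
    abort(sprintf(
      "illegal character outside {A,C,G,T,N,U} in FASTA line %d: %s",
      bad[1], lines[bad[1]]
    ))
  }
  headers <- which(is_header)
  ids <- sub("^>\\s*", "", lines[headers])
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids))) {
    abort(sprintf("malformed FASTA: empty header at line %d",
                  headers[which(!nzchar(ids))[1]]))
  }
  bounds <- c(headers, length(lines) + 1L)
  seqs <- vapply(seq_along(headers), function(i) {
    body <- lines[setdiff(seq(bounds[i] + 1L, bounds[i + 1L] - 1L),
                          integer(0))]
    paste(trimws(body), collapse = "")
  }, character(1))
  tibble::tibble(seq_id = ids, region = region,
                 sequence = normalize_sequence(seqs))
}

#' Write a sequence table to FASTA
#'
#' @param seqs A sequence table with columns `seq_id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width in nucleotides.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  check_seq_tbl(seqs)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", seqs$seq_id[i]), con)
    s <- seqs$sequence[i]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Keep the longest isoform per gene
#'
#' When a gene contributes several isoform sequences for the same region,
#' only the longest is retained.  Length ties are broken deterministically by
#' keeping the lexicographically smallest sequence.
#'
#' @param seqs A sequence table (`seq_id`, `sequence`, optionally `region`).
#' @return A sequence table with exactly one row per `seq_id`, ordered by
#'   first appearance of each id.
#' @export
collapse_isoforms <- function(seqs) {
  check_seq_tbl(seqs)
  seqs |>
    dplyr::mutate(.orig = dplyr::row_number()) |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::arrange(dplyr::desc(nchar(.data$sequence)), .data$sequence,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.orig) |>
    dplyr::select(-".orig")
}

#' Construct a motif count matrix
#'
#' @param motif_id Motif identifier.
#' @param name Motif (factor) name.
#' @param counts 4 x L numeric matrix of non-negative counts, rows A,C,G,T.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(motif_id, name, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) abort("count matrix must have 4 rows (A,C,G,T)")
  if (ncol(counts) < 1) abort("count matrix must have at least one column")
  if (any(is.na(counts)) || any(counts < 0)) {
    abort("count matrix entries must be non-negative numbers")
  }
  if (any(colSums(counts) == 0)) {
    abort("every count-matrix column must contain a positive count")
  }
  rownames(counts) <- DNA_BASES
  structure(list(motif_id = motif_id, name = name, counts = counts),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %s (%s), %d positions\n",
              x$motif_id, x$name, ncol(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Read JASPAR-format count matrices
#'
#' Accepts both common JASPAR PFM dialects: four bare rows of numbers in
#' A,C,G,T order, or labelled rows such as `A [ 10 0 5 ]`.  Row order is
#' normalized to A,C,G,T.
#'
#' @param path Path to a JASPAR PFM file (one or more matrices).
#' @return A list of [count_matrix()] objects.
#' @export
read_jaspar <- function(path) {
  if (!file.exists(path)) abort(sprintf("JASPAR file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- trimws(lines[keep])
  headers <- which(startsWith(lines, ">"))
  if (length(headers) == 0) {
    if (length(lines) == 0) return(list())
    abort("malformed JASPAR file: no '>' header found")
  }
  bounds <- c(headers, length(lines) + 1L)
  out <- vector("list", length(headers))
  for (i in seq_along(headers)) {
    hdr <- sub("^>\\s*", "", lines[headers[i]])
    toks <- strsplit(hdr, "\\s+")[[1]]
    motif_id <- toks[1]
    name <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else toks[1]
    body <- lines[setdiff(seq(bounds[i] + 1L, bounds[i + 1L] - 1L),
                          integer(0))]
    if (length(body) != 4) {
      abort(sprintf(
        "malformed JASPAR matrix '%s' (near line %d): expected 4 rows, got %d",
        motif_id, line_no[headers[i]], length(body)
      ))
    }
    labelled <- grepl("^[ACGTacgt]\\b", body) | grepl("^[ACGTacgt]\\s*\\[",
                                                      body)
    rows <- lapply(body, function(l) {
      l <- sub("^[ACGTacgt]", "", l)
      l <- gsub("[][]", " ", l)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (any(is.na(vals))) {
        abort(sprintf("malformed JASPAR matrix '%s': non-numeric counts",
                      motif_id))
      }
      vals
    })
    if (length(unique(lengths(rows))) != 1) {
      abort(sprintf("malformed JASPAR matrix '%s': ragged columns", motif_id))
    }
    counts <- do.call(rbind, rows)
    if (all(labelled)) {
      labels <- toupper(substr(body, 1, 1))
      if (!setequal(labels, DNA_BASES)) {
        abort(sprintf("malformed JASPAR matrix '%s': row labels must be A,C,G,T",
                      motif_id))
      }
      counts <- counts[match(DNA_BASES, labels), , drop = FALSE]
    } else if (any(labelled)) {
      abort(sprintf("malformed JASPAR matrix '%s': mixed row dialects",
                    motif_id))
    }
    out[[i]] <- count_matrix(motif_id, name, counts)
  }
  names(out) <- vapply(out, function(m) m$motif_id, character(1))
  out
}

#' Read a differential-expression table
#'
#' Expects a tab-separated file with header columns `gene_id`, `logFC`,
#' `p` and `fdr`.  Gene ids must be unique; `p` and `fdr` must lie in
#' \[0, 1\].
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `gene_id`, `logFC`, `p`, `fdr`.
#' @export
read_diff_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  missing_cols <- setdiff(c("gene_id", "logFC", "p", "fdr"), names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("differential table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  tbl <- tbl[, c("gene_id", "logFC", "p", "fdr")]
  if (anyNA(tbl$logFC) || anyNA(tbl$p) || anyNA(tbl$fdr)) {
    abort("differential table contains non-numeric or missing values")
  }
  dup <- tbl$gene_id[duplicated(tbl$gene_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate gene_id in differential table: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  if (any(tbl$p < 0 | tbl$p > 1) || any(tbl$fdr < 0 | tbl$fdr > 1)) {
    abort("p and fdr values must lie in [0, 1]")
  }
  tbl
}

#' Write a result table with a parameter header
#'
#' Writes any result tibble as TSV, prefixed with `#`-commented header lines
#' recording the analysis parameters stored in the table's attributes
#' (word length `k`, shuffle count `B`, permutation count `P`, `seed`,
#' `metric`, thresholds), so outputs are self-describing.
#'
#' @param result A result tibble (e.g. from [word_analysis()],
#'   [seed_enrichment()] or [promoter_enrichment()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_enrichment_table()]
#' @export
write_enrichment_table <- function(result, path) {
  if (!is.data.frame(result)) abort("`result` must be a data frame")
  params <- attributes(result)[c("k", "B", "P", "seed", "metric", "threshold",
                                 "fdr_regulated", "fdr_nochange", "strands")]
  params <- params[!vapply(params, is.null, logical(1))]
  writeLines(vapply(names(params), function(nm) {
    sprintf("# %s: %s", nm, paste(params[[nm]], collapse = ","))
  }, character(1)), path)
  readr::write_tsv(tibble::as_tibble(result), path, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read a result table written by [write_enrichment_table()]
#'
#' @param path Path to a TSV file with `#`-commented parameter header.
#' @return A tibble; recovered parameters are attached as attributes.
#' @export
read_enrichment_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  tbl <- readr::read_tsv(I(lines[!startsWith(lines, "#")]),
                         col_types = readr::cols(), progress = FALSE)
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) {
      val <- m[3]
      num <- suppressWarnings(as.numeric(val))
      attr(tbl, trimws(m[2])) <- if (!is.na(num)) num else val
    }
  }
  tbl
}
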