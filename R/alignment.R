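#' DNA alignment objects
#'
#' A `dna_alignment` is a taxa x sites character matrix over the nucleotide
#' alphabet `A C G T`, the gap character `-`, `?`, and the IUPAC ambiguity
#' codes (`R Y S W K M B D H V N`). Row names are the (unique) taxon labels.
#' Columns are alignment sites, indexed 1-based throughout the package.
#' An optional `frame` attribute gives the codon phase (1, 2 or 3) of
#' column 1, used by codon-position bookkeeping.
#'
#' @param x character matrix of single characters, with row names.
#' @param frame optional codon phase (1, 2 or 3) of the first column.
#' @return A `dna_alignment` object.
#' @export
dna_alignment <- function(x, frame = NULL) {
  if (!is.matrix(x) || !is.character(x))
    stop("'x' must be a character matrix of single characters")
  taxa <- rownames(x)
  if (is.null(taxa) || anyNA(taxa) || any(!nzchar(taxa)))
    stop("alignment rows must be named with non-empty taxon labels")
  if (anyDuplicated(taxa))
    stop("duplicate taxon label: ", taxa[duplicated(taxa)][1L])
  if (ncol(x) < 1L) stop("alignment must have at least one site")
  x[] <- toupper(x)
  x[x == "U"] <- "T"
  bad <- which(!(x %in% DNA_ALPHABET))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(x)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(x)) + 1L
    stop(sprintf("illegal character '%s' in taxon '%s', column %d",
                 x[bad[1L]], taxa[i], j))
  }
  if (!is.null(frame)) {
    frame <- as.integer(frame)
    if (!frame %in% 1:3) stop("'frame' must be 1, 2 or 3")
  }
  structure(x, frame = frame, class = c("dna_alignment", "matrix", "array"))
}

DNA_ALPHABET <- c("A", "C", "G", "T", "-", "?",
                  "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("DNA alignment: %d taxa, %d sites", nrow(x), ncol(x)))
  if (!is.null(attr(x, "frame")))
    cat(sprintf(" (codon phase of column 1: %d)", attr(x, "frame")))
  cat("\n")
  show <- utils::head(rownames(x), 5L)
  for (tx in show)
    cat(sprintf("  %-12s %s%s\n", tx,
                paste(x[tx, seq_len(min(50L, ncol(x)))], collapse = ""),
                if (ncol(x) > 50L) "..." else ""))
  if (nrow(x) > 5L) cat(sprintf("  ... and %d more\n", nrow(x) - 5L))
  invisible(x)
}

#' Number of sites and taxon labels of an alignment
#' @param x a `dna_alignment`.
#' @return `n_sites()`: integer site count; `taxa_labels()`: character vector.
#' @export
n_sites <- function(x) ncol(x)

#' @rdname n_sites
#' @export
taxa_labels <- function(x) rownames(x)

#' Read an aligned FASTA file
#'
#' Sequences are uppercased and `U` is mapped to `T`. All sequences must
#' have equal length (the input is an alignment, not raw reads).
#'
#' @param path path to an aligned FASTA file (gaps as `-`).
#' @param frame optional codon phase (1|2|3) of column 1.
#' @return A [dna_alignment].
#' @export
read_fasta <- function(path, frame = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1L]) stop("not a FASTA file: ", path)
  idx <- cumsum(hdr)
  labels <- trimws(sub("^>", "", lines[hdr]))
  labels <- vapply(strsplit(labels, "[ \t]"), `[`, "", 1L)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(s) paste(trimws(s), collapse = ""), "")
  if (length(seqs) != length(labels)) stop("FASTA record with no sequence")
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    off <- labels[which(lens != lens[1L])[1L]]
    stop(sprintf("sequences are not aligned: '%s' has length %d, expected %d",
                 off, lens[lens != lens[1L]][1L], lens[1L]))
  }
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- labels
  dna_alignment(m, frame = frame)
}

#' Write an alignment to FASTA
#'
#' Round-trips with [read_fasta()]: `read_fasta(write_fasta(a, f))` equals `a`.
#'
#' @param alignment a [dna_alignment].
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(alignment, path, width = 60L) {
  stopifnot(inherits(alignment, "dna_alignment"))
  if (nrow(alignment) < 1L) stop("alignment has no taxa")
  con <- file(path, "w")
  on.exit(close(con))
  for (tx in rownames(alignment)) {
    s <- paste(alignment[tx, ], collapse = "")
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", tx), substring(s, starts,
                                            pmin(starts + width - 1L, nchar(s)))),
               con)
  }
  invisible(path)
}

#' Count columns free of gap characters
#'
#' The "gapless length" of a gene: the number of alignment columns in which
#' no sequence has a gap (`-`). Used as the length axis of the
#' length-informativeness regression.
#'
#' @param alignment a [dna_alignment].
#' @return Integer count of completely gap-free columns.
#' @export
gapless_length <- function(alignment) {
  stopifnot(inherits(alignment, "dna_alignment"))
  sum(colSums(unclass(alignment) == "-") == 0L)
}

#' Split a combined alignment into taxon groups
#'
#' Mirrors the combined-then-split workflow used to make site coordinates
#' comparable across shallow and deep taxon sets: every sub-alignment keeps
#' all columns of the combined alignment (identity coordinate map), so site
#' indices remain directly comparable between groups. Columns in which a
#' group has more gap sequences than `gap_frac` (or only gaps) are flagged
#' as indel-rich, not removed.
#'
#' @param combined a [dna_alignment].
#' @param groups named list of taxon-label vectors; together they must be a
#'   partition of a subset of the combined taxa (no taxon in two groups).
#' @param gap_frac fraction of gap sequences above which a column is
#'   flagged indel-rich within a group (default 0.5).
#' @return Named list of `dna_alignment` objects; each carries attributes
#'   `coord_map` (identity map to combined columns), `gap_only` (logical,
#'   all-gap within group) and `indel_rich` (logical, gap fraction >
#'   `gap_frac`).
#' @export
split_alignment <- function(combined, groups, gap_frac = 0.5) {
  stopifnot(inherits(combined, "dna_alignment"), is.list(groups))
  all_g <- unlist(groups, use.names = FALSE)
  unknown <- setdiff(all_g, rownames(combined))
  if (length(unknown)) stop("unknown taxon in partition: ", unknown[1L])
  if (anyDuplicated(all_g)) stop("taxon assigned to more than one group")
  lapply(groups, function(tx) {
    sub <- dna_alignment(unclass(combined)[tx, , drop = FALSE],
                         frame = attr(combined, "frame"))
    gf <- colMeans(unclass(sub) == "-")
    attr(sub, "coord_map") <- seq_len(ncol(combined))
    attr(sub, "gap_only") <- gf == 1
    attr(sub, "indel_rich") <- gf > gap_frac
    sub
  })
}
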