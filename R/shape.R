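# DNA-shape-conditioned GCG counting.  Helix twist is modeled at the
# base-pair-step level from a pentamer table: the step between sequence
# positions i and i+1 (0-based) takes the twist of the pentamer covering
# positions i-1 .. i+3, i.e. two bases of context on each side of the step.
# A GCG trinucleotide at position p spans two internal steps, (p, p+1) and
# (p+1, p+2); the hit matches the recruitment-permissive shape when the
# mean twist over those steps is strictly below the threshold.  Minus-strand
# hits (CGC on the forward strand) are evaluated on the reverse-complement
# sequence's own pentamers, never by reusing forward-strand values.

DNA_BASES <- c("A", "C", "G", "T")

#' Deterministic synthetic pentamer twist table
#'
#' A complete 1,024-entry pentamer-to-twist table generated from a seeded
#' integer hash of each pentamer string, mapped to a realistic B-DNA twist
#' range (28 to 40 degrees). Purely synthetic: it stands in for a
#' measured pentamer shape model so the counting machinery can be tested
#' without an external shape database, and it is labelled as such.
#'
#' @param seed integer mixed into the hash (default 1).
#' @return data.frame with columns \code{pentamer}, \code{twist}.
#' @export
synthetic_shape_table <- function(seed = 1L) {
  idx <- expand.grid(DNA_BASES, DNA_BASES, DNA_BASES, DNA_BASES, DNA_BASES,
                     stringsAsFactors = FALSE)
  pent <- apply(idx[, 5:1], 1L, paste, collapse = "")
  code <- vapply(pent, function(p) {
    b <- match(strsplit(p, "")[[1L]], DNA_BASES) - 1L
    sum(b * 4^(0:4))
  }, 0)
  h <- (1103515245 * (code + as.double(seed)) + 12345) %% 2^31
  data.frame(pentamer = pent, twist = 28 + 12 * h / 2^31,
             stringsAsFactors = FALSE)
}

#' Load a pentamer twist table
#'
#' Two-column TSV (pentamer, twist in degrees). The table must contain all
#' 1,024 ACGT pentamers unless a \code{default} twist is declared for the
#' missing ones; duplicated pentamers are an error.
#'
#' @param path TSV file with columns pentamer, twist (header optional).
#' @param default optional twist used for pentamers absent from the file.
#' @return named numeric vector of length 1,024 (twist by pentamer).
#' @export
load_shape_table <- function(path, default = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("pentamer", "twist"),
                          colClasses = c("character", "numeric"))
  if (identical(toupper(df$pentamer[1L]), "PENTAMER"))
    df <- df[-1L, , drop = FALSE]
  df$twist <- as.numeric(df$twist)
  df$pentamer <- toupper(df$pentamer)
  if (any(!grepl("^[ACGT]{5}$", df$pentamer)))
    stopf("invalid pentamer(s): %s",
          paste(utils::head(df$pentamer[!grepl("^[ACGT]{5}$", df$pentamer)], 3L),
                collapse = ", "))
  if (anyDuplicated(df$pentamer))
    stopf("duplicate pentamer(s): %s",
          paste(unique(df$pentamer[duplicated(df$pentamer)]), collapse = ", "))
  if (any(!is.finite(df$twist))) stopf("non-finite twist value(s)")
  tab <- stats::setNames(df$twist, df$pentamer)
  all_pent <- synthetic_shape_table()$pentamer
  miss <- setdiff(all_pent, names(tab))
  if (length(miss)) {
    if (is.null(default))
      stopf("%d pentamer(s) missing and no default declared", length(miss))
    tab[miss] <- default
  }
  tab[all_pent]
}

#' Write a pentamer twist table as TSV
#' @param table named numeric vector or data.frame(pentamer, twist).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_shape_table <- function(table, path) {
  if (is.data.frame(table))
    table <- stats::setNames(table$twist, table$pentamer)
  utils::write.table(
    data.frame(pentamer = names(table), twist = unname(table)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

as_shape_vector <- function(table) {
  if (is.data.frame(table)) stats::setNames(table$twist, table$pentamer)
  else table
}

#' Scan a sequence for GCG trinucleotides
#'
#' Forward-strand GCG occurrences plus CGC occurrences (the reverse
#' complement of GCG) reported as minus-strand hits. Case-insensitive;
#' windows containing N never match.
#'
#' @param sequence character string or \code{Biostrings::DNAString} over
#'   the ACGTN alphabet.
#' @return data.frame with columns \code{start} (0-based position on the
#'   forward strand) and \code{strand} ("+" or "-"), ordered by position.
#' @export
scan_gcg <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (!nzchar(s))
    return(data.frame(start = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  if (grepl("[^ACGTN]", s)) stopf("sequence contains non-ACGTN characters")
  dna <- Biostrings::DNAString(s)
  fwd <- Biostrings::start(Biostrings::matchPattern("GCG", dna)) - 1L
  rev <- Biostrings::start(Biostrings::matchPattern("CGC", dna)) - 1L
  out <- data.frame(start = c(fwd, rev),
                    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
                    stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

# mean twist over the two internal steps of a trinucleotide at 0-based
# position p of sequence s (plain character); NA when the required
# pentamers run past the sequence (or hit an N).
trinuc_mean_twist <- function(s, p, table) {
  L <- nchar(s)
  if (p < 1L || p + 4L > L - 1L) return(NA_real_)
  pent1 <- substr(s, p, p + 4L)        # 1-based: (p-1..p+3 0-based)
  pent2 <- substr(s, p + 1L, p + 5L)   # (p .. p+4 0-based)
  t1 <- table[pent1]; t2 <- table[pent2]
  if (is.na(t1) || is.na(t2)) return(NA_real_)
  unname((t1 + t2) / 2)
}

count_shape_matching_fwd <- function(s, table, twist_threshold) {
  dna <- Biostrings::DNAString(s)
  pos0 <- Biostrings::start(Biostrings::matchPattern("GCG", dna)) - 1L
  if (!length(pos0))
    return(list(total = 0L, matching = 0L, edge_skipped = 0L))
  tw <- vapply(pos0, function(p) trinuc_mean_twist(s, p, table), 0)
  edge <- is.na(tw)
  list(total = length(pos0),
       matching = sum(tw[!edge] < twist_threshold),
       edge_skipped = sum(edge))
}

#' Count GCG trinucleotides matching the DNA-shape requirement
#'
#' Counts all GCG occurrences (both strands) in a region and how many
#' match the recruitment-permissive shape: mean pentamer-model helix twist
#' over the trinucleotide's two internal base-pair steps strictly below
#' \code{twist_threshold}. Minus-strand hits are scored on the
#' reverse-complement sequence. Hits whose context pentamers run past the
#' sequence edge are excluded from shape scoring under
#' \code{flank_mode = "strict"} and tallied in \code{edge_skipped}.
#'
#' @param sequence character string or \code{DNAString} (length >= 5).
#' @param table pentamer twist table (named vector or data.frame from
#'   \code{\link{synthetic_shape_table}} / \code{\link{load_shape_table}}).
#' @param twist_threshold twist cutoff in degrees; defaults to the
#'   table-wide median (a placeholder default, to be overridden when a
#'   calibrated cutoff is available).
#' @param flank_mode \code{"strict"}: edge hits are excluded and tallied.
#' @param region_id optional region label.
#' @return one-row data.frame (class \code{MotifCount} semantics):
#'   region_id, length_bp, total_gcg, shape_matching_gcg, edge_skipped,
#'   density (shape-matching GCG per kb).
#' @export
count_shape_matching <- function(sequence, table, twist_threshold = NULL,
                                 flank_mode = c("strict"),
                                 region_id = NA_character_) {
  flank_mode <- match.arg(flank_mode)
  s <- toupper(as.character(sequence))
  if (nchar(s) < 5L) stopf("sequence must be at least 5 bp")
  if (grepl("[^ACGTN]", s)) stopf("sequence contains non-ACGTN characters")
  tab <- as_shape_vector(table)
  twist_threshold <- twist_threshold %||% stats::median(tab)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  f <- count_shape_matching_fwd(s, tab, twist_threshold)
  r <- count_shape_matching_fwd(rc, tab, twist_threshold)
  data.frame(region_id = region_id, length_bp = nchar(s),
             total_gcg = f$total + r$total,
             shape_matching_gcg = f$matching + r$matching,
             edge_skipped = f$edge_skipped + r$edge_skipped,
             density = (f$matching + r$matching) / (nchar(s) / 1000),
             stringsAsFactors = FALSE)
}

#' Shape-matching GCG counts for every peak in a region set
#'
#' @param sequences named \code{Biostrings::DNAStringSet} (chromosome
#'   sequences) or a FASTA file path.
#' @param peaks a \code{PeakSet}.
#' @param table pentamer twist table.
#' @param twist_threshold,flank_mode see \code{\link{count_shape_matching}}.
#' @return data.frame, one row per peak (row order = peak order).
#' @export
region_shape_counts <- function(sequences, peaks, table,
                                twist_threshold = NULL,
                                flank_mode = "strict") {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences))
    sequences <- Biostrings::readDNAStringSet(sequences)
  df <- as.data.frame(peaks)
  miss <- setdiff(unique(df$chrom), names(sequences))
  if (length(miss))
    stopf("peak chromosome(s) absent from sequences: %s",
          paste(miss, collapse = ", "))
  ids <- peak_ids(peaks)
  out <- lapply(seq_len(nrow(df)), function(i) {
    s <- Biostrings::subseq(sequences[[df$chrom[i]]],
                            start = df$start[i] + 1L, end = df$end[i])
    count_shape_matching(s, table, twist_threshold, flank_mode,
                         region_id = ids[i])
  })
  do.call(rbind, out)
}
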