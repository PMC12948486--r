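#' Motif verification for sulfite-reductase catalytic subunits
#'
#' Checks a protein sequence for the conserved siroheme-binding
#' `CX5CXnCX3C` motif (with `n` bounded to 1-300 residues so the scan is
#' well defined) and the `[Fe4S4]` cluster-binding `CX2CX2C` motif.
#' Case-insensitive.
#'
#' @param sequence Amino-acid string (20 residues plus `X`; gaps `-`
#'   are tolerated and ignored).
#' @return Named logical vector `c(siroheme_ok, fe4s4_ok)`.
#' @export
motif_screen <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  s <- toupper(gsub("-", "", sequence))
  bad <- setdiff(unique(strsplit(s, "")[[1]]), c(AA20, "X"))
  if (length(bad)) {
    stop("non-residue character(s) in sequence: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  c(siroheme_ok = grepl("C.{5}C.{1,300}?C.{3}C", s, perl = TRUE),
    fe4s4_ok = grepl("C.{2}C.{2}C", s, perl = TRUE))
}

#' Pair adjacent A/B subunit genes
#'
#' Retains every A/B pair lying at consecutive `gene_index` on the same
#' contig of the same genome (either order). A record joins at most one
#' pair: when a record is adjacent to two partners, the partner whose
#' sequence passes more motif checks wins, then the smaller `gene_index`.
#' Unpaired records are dropped and counted.
#'
#' @param records Data.frame with columns `id`, `genome_id`, `contig_id`,
#'   `gene_index`, `subunit` (`"A"`/`"B"`), `sequence`.
#' @param motif_subunit Which subunit(s) must pass both motifs for the pair
#'   to be flagged `motif_ok`: `"A"` (default, the reference behaviour),
#'   `"AB"`, or `"none"`.
#' @return Data.frame of pairs: a_id, b_id, genome_id, contig_id,
#'   concat_sequence, motif_ok; attribute `n_unpaired`.
#' @export
pair_adjacent <- function(records, motif_subunit = c("A", "AB", "none")) {
  motif_subunit <- match.arg(motif_subunit)
  need <- c("id", "genome_id", "contig_id", "gene_index", "subunit", "sequence")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  key <- paste(records$genome_id, records$contig_id, records$gene_index)
  if (anyDuplicated(key)) {
    stop("duplicate (genome, contig, gene_index): ",
         key[duplicated(key)][1], call. = FALSE)
  }
  motifs_ok <- function(seq) all(motif_screen(seq))
  used <- logical(nrow(records))
  pairs <- NULL
  aidx <- which(records$subunit == "A")
  # deterministic processing order
  aidx <- aidx[order(records$genome_id[aidx], records$contig_id[aidx],
                     records$gene_index[aidx])]
  for (i in aidx) {
    if (used[i]) next
    cand <- which(!used & records$subunit == "B" &
                    records$genome_id == records$genome_id[i] &
                    records$contig_id == records$contig_id[i] &
                    abs(records$gene_index - records$gene_index[i]) == 1)
    if (!length(cand)) next
    if (length(cand) > 1) {
      sc <- vapply(cand, function(j) sum(motif_screen(records$sequence[j])),
                   numeric(1))
      cand <- cand[order(-sc, records$gene_index[cand])]
    }
    j <- cand[1]
    used[i] <- used[j] <- TRUE
    mok <- switch(motif_subunit,
      A = motifs_ok(records$sequence[i]),
      AB = motifs_ok(records$sequence[i]) && motifs_ok(records$sequence[j]),
      none = TRUE)
    pairs <- rbind(pairs, data.frame(
      a_id = records$id[i], b_id = records$id[j],
      genome_id = records$genome_id[i], contig_id = records$contig_id[i],
      concat_sequence = paste0(records$sequence[i], records$sequence[j]),
      motif_ok = mok, stringsAsFactors = FALSE))
  }
  if (is.null(pairs)) {
    pairs <- data.frame(a_id = character(0), b_id = character(0),
                        genome_id = character(0), contig_id = character(0),
                        concat_sequence = character(0), motif_ok = logical(0),
                        stringsAsFactors = FALSE)
  }
  attr(pairs, "n_unpaired") <- sum(!used)
  pairs
}

#' Full candidate screen on a sequence set with metadata
#'
#' Applies [pair_adjacent()] and keeps only motif-positive pairs.
#'
#' @inheritParams pair_adjacent
#' @return The motif-positive subset of the pair table.
#' @export
screen_candidates <- function(records, motif_subunit = "A") {
  p <- pair_adjacent(records, motif_subunit)
  out <- p[p$motif_ok, , drop = FALSE]
  attr(out, "n_unpaired") <- attr(p, "n_unpaired")
  attr(out, "n_motif_fail") <- sum(!p$motif_ok)
  out
}

#' Global pairwise protein identity
#'
#' Needleman-Wunsch global alignment with BLOSUM62 scoring, gap open 11 /
#' extend 1, terminal gaps free. Identity = matches / alignment columns
#' excluding terminal gaps. Symmetric and exactly 1 on identical inputs.
#'
#' @param x,y Non-empty amino-acid strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(x, y) {
  stopifnot(nzchar(x), nzchar(y))
  if (identical(toupper(x), toupper(y))) return(1)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(x)), Biostrings::AAString(toupper(y)),
    type = "overlap", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ncols <- length(pa)
  if (ncols == 0) return(0)
  sum(pa == sa & pa != "-") / ncols
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Greedy longest-first redundancy clustering
#'
#' Sequences are sorted longest first (ties by name); each sequence joins
#' the first representative it matches at >= `threshold` identity, else
#' founds a new cluster. Mirrors the threshold semantics of greedy
#' incremental clustering tools without their word-size speed heuristics.
#'
#' @param sequences Named character vector.
#' @param threshold Identity threshold in `(0, 1]` (default 0.75).
#' @return Data.frame: id, representative, cluster (integer), identity to
#'   the representative.
#' @export
greedy_cluster <- function(sequences, threshold = 0.75) {
  stopifnot(threshold > 0, threshold <= 1, !is.null(names(sequences)))
  ord <- order(-nchar(sequences), names(sequences))
  reps <- character(0)
  out <- NULL
  for (i in ord) {
    id <- names(sequences)[i]
    assigned <- FALSE
    for (r in reps) {
      idn <- pairwise_identity(sequences[[i]], sequences[[r]])
      if (idn >= threshold) {
        out <- rbind(out, data.frame(id = id, representative = r,
                                     identity = idn, stringsAsFactors = FALSE))
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, id)
      out <- rbind(out, data.frame(id = id, representative = id,
                                   identity = 1, stringsAsFactors = FALSE))
    }
  }
  out$cluster <- match(out$representative, reps)
  out[order(match(out$id, names(sequences))), c("id", "representative",
                                                "cluster", "identity")]
}

#' Single-linkage clade assignment from an identity matrix
#'
#' Clades are the connected components of the graph joining members with
#' identity >= `threshold`. Labels are deterministic: each clade is named
#' after its lexicographically smallest member.
#'
#' @param identity_matrix Square symmetric matrix with unit diagonal and
#'   row/col names.
#' @param threshold Identity threshold (default 0.60).
#' @return Named character vector member -> clade label; attribute
#'   `threshold`.
#' @export
assign_clades <- function(identity_matrix, threshold = 0.60) {
  m <- as.matrix(identity_matrix)
  stopifnot(nrow(m) == ncol(m), !is.null(rownames(m)))
  if (max(abs(m - t(m))) > 1e-9) {
    stop("identity matrix is asymmetric beyond tolerance 1e-9", call. = FALSE)
  }
  g <- igraph::graph_from_adjacency_matrix(m >= threshold, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  labels <- vapply(split(names(comp), comp), function(ids) min(ids), "")
  out <- stats::setNames(labels[as.character(comp)], names(comp))
  out <- out[rownames(m)]
  attr(out, "threshold") <- threshold
  out
}
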