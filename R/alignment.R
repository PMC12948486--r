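#' Read / write a protein alignment as FASTA
#'
#' Alignments are plain character matrices (rows = taxa, columns = sites,
#' uppercase residues, gap `"-"`).
#'
#' @param path FASTA file path.
#' @return `read_alignment`: character matrix with taxa as rownames.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  as_alignment(stats::setNames(as.character(ss), names(ss)))
}

#' @rdname read_alignment
#' @param aln Alignment matrix (or named character vector of equal-length
#'   sequences).
#' @export
write_alignment <- function(aln, path) {
  aln <- as_alignment(aln)
  seqs <- apply(aln, 1, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' @rdname read_alignment
#' @export
as_alignment <- function(aln) {
  if (is.matrix(aln)) {
    m <- toupper(aln)
  } else {
    stopifnot(is.character(aln), !is.null(names(aln)))
    w <- unique(nchar(aln))
    if (length(w) != 1) stop("sequences have unequal lengths; not an alignment",
                             call. = FALSE)
    m <- do.call(rbind, strsplit(toupper(aln), ""))
    rownames(m) <- names(aln)
  }
  if (is.null(rownames(m))) stop("alignment rows must be named", call. = FALSE)
  m
}

aln_gap_mask <- function(aln) aln == "-" | aln == "." | aln == "X"

#' Drop low-occupancy alignment columns with a retention floor
#'
#' Keeps columns whose non-gap fraction is at least `occupancy`. If fewer
#' than `ceiling(min_fraction * ncol)` columns survive, the highest-occupancy
#' dropped columns (ties broken leftmost) are added back until exactly that
#' floor is kept. Column order is preserved.
#'
#' @param aln Alignment matrix.
#' @param occupancy Minimum non-gap fraction per kept column (default 0.95).
#' @param min_fraction Floor on the fraction of original columns retained
#'   (default 0.50).
#' @return Filtered alignment; attribute `kept` holds the column indices.
#'   The operation is idempotent whenever the occupancy rule alone retains
#'   at least the floor; once the floor engages, a second pass re-drops
#'   the added-back low-occupancy columns.
#' @export
trim_gaps <- function(aln, occupancy = 0.95, min_fraction = 0.50) {
  aln <- as_alignment(aln)
  if (ncol(aln) == 0 || nrow(aln) == 0) stop("empty alignment", call. = FALSE)
  stopifnot(occupancy >= 0, occupancy <= 1, min_fraction >= 0, min_fraction <= 1)
  occ <- 1 - colMeans(aln == "-")
  keep <- occ >= occupancy
  floor_n <- ceiling(min_fraction * ncol(aln))
  if (sum(keep) < floor_n) {
    dropped <- which(!keep)
    ord <- dropped[order(-occ[dropped], dropped)]
    keep[ord[seq_len(floor_n - sum(keep))]] <- TRUE
  }
  out <- aln[, keep, drop = FALSE]
  attr(out, "kept") <- which(keep)
  out
}

#' Remove the most compositionally heterogeneous alignment columns
#'
#' Scores each column by the chi-square statistic of its residue counts
#' against the alignment-wide residue frequencies (gaps ignored) and removes
#' the top `remove_fraction` of columns (ties removed leftmost first), so
#' that exactly `ceiling((1 - remove_fraction) * ncol)` columns survive.
#'
#' @param aln Alignment matrix.
#' @param remove_fraction Fraction of columns to remove, in `[0, 1)`;
#'   the reference analysis grid spans 0 to 0.40.
#' @return Filtered alignment; attribute `kept` holds the column indices.
#' @export
prune_heterogeneous_sites <- function(aln, remove_fraction) {
  aln <- as_alignment(aln)
  if (remove_fraction >= 1) stop("remove_fraction must be < 1", call. = FALSE)
  stopifnot(remove_fraction >= 0)
  n <- ncol(aln)
  n_keep <- as.integer(ceiling((1 - remove_fraction) * n))
  if (n_keep == n) {
    attr(aln, "kept") <- seq_len(n)
    return(aln)
  }
  res <- !aln_gap_mask(aln)
  glob <- table(factor(aln[res], levels = AA20))
  glob <- glob / sum(glob)
  score <- vapply(seq_len(n), function(j) {
    col <- aln[res[, j], j]
    if (!length(col)) return(0)
    o <- table(factor(col, levels = AA20))
    e <- glob * length(col)
    ok <- e > 0
    sum((o[ok] - e[ok])^2 / e[ok])
  }, numeric(1))
  drop <- order(-score, seq_len(n))[seq_len(n - n_keep)]
  keep <- setdiff(seq_len(n), drop)
  out <- aln[, keep, drop = FALSE]
  attr(out, "kept") <- keep
  out
}

#' Pairwise distances from a protein alignment
#'
#' Distances are computed over mutually ungapped columns (gap and `X`
#' treated as missing). Models: `"p"` (mismatch fraction), `"poisson"`
#' (`-log(1 - p)`), `"gamma"` (`shape * ((1 - p)^(-1/shape) - 1)`).
#' Saturated pairs (`p >= 0.95`) are clamped to the distance at `p = 0.95`
#' and flagged in the `saturated` attribute.
#'
#' @param aln Alignment matrix (>= 2 rows).
#' @param model `"p"`, `"poisson"` or `"gamma"`.
#' @param shape Gamma shape (required for `model = "gamma"`).
#' @param p_max Saturation clamp (default 0.95).
#' @return Symmetric matrix with zero diagonal, `model` and `saturated`
#'   attributes.
#' @export
distance_matrix <- function(aln, model = c("poisson", "p", "gamma"),
                            shape = NULL, p_max = 0.95) {
  aln <- as_alignment(aln)
  model <- match.arg(model)
  if (nrow(aln) < 2) stop("need at least 2 sequences", call. = FALSE)
  if (model == "gamma" && (is.null(shape) || shape <= 0))
    stop("gamma model needs a positive shape", call. = FALSE)
  n <- nrow(aln)
  ok <- !aln_gap_mask(aln)
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  sat <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- ok[i, ] & ok[j, ]
      if (!any(shared)) {
        stop("no mutually ungapped columns for pair ", rownames(aln)[i],
             " / ", rownames(aln)[j], call. = FALSE)
      }
      p <- mean(aln[i, shared] != aln[j, shared])
      if (p >= p_max) {
        sat <- rbind(sat, c(rownames(aln)[i], rownames(aln)[j]))
        p <- p_max
      }
      d <- switch(model,
        p = p,
        poisson = -log(1 - p),
        gamma = shape * ((1 - p)^(-1 / shape) - 1))
      D[i, j] <- D[j, i] <- d
    }
  }
  attr(D, "model") <- if (model == "gamma") sprintf("gamma(%g)", shape) else model
  attr(D, "saturated") <- sat
  D
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d Matrix from [distance_matrix()].
#' @param path Output path.
#' @export
write_phylip_dist <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format(nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(c(rownames(d)[i], format(d[i, ], digits = 10)),
                     collapse = "  "), con)
  }
  invisible(path)
}
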