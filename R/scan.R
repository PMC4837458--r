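#' Position score matrix for the dPPR repeat scaffold
#'
#' Builds a 35 x 20 log2-odds matrix (vs uniform amino-acid background)
#' from the scaffold consensus. Columns 5 and 35 are the free code slots
#' and score 0 for every residue; all other columns place most of the
#' probability mass on the consensus letter, with a pseudocount spreading
#' the rest so degenerate natural repeats are tolerated.
#'
#' @param scaffold a `ppr_scaffold`
#' @param pseudocount total pseudocount mass spread over the 20 residues
#'   at each column (default 0.5)
#' @return a 35 x 20 numeric matrix (rows = repeat positions, columns =
#'   amino acids in `AGCT...` one-letter order) with attribute `max_score`
#' @export
build_repeat_pssm <- function(scaffold, pseudocount = 0.5) {
  stopifnot(inherits(scaffold, "ppr_scaffold"), pseudocount >= 0)
  cons <- strsplit(scaffold$template, "")[[1]]
  m <- matrix(0, nrow = 35L, ncol = 20L, dimnames = list(NULL, AA1))
  for (j in seq_len(35L)) {
    if (j %in% scaffold$slot_positions) next
    p <- rep(pseudocount / 20, 20L)
    p[match(cons[j], AA1)] <- p[match(cons[j], AA1)] + 1
    p <- p / (1 + pseudocount)
    m[j, ] <- log2(p / (1 / 20))
  }
  attr(m, "max_score") <- sum(apply(m, 1, max))
  m
}

# Sliding-window PSSM scores for every start position (stride 1).
.window_scores <- function(seq_chars, pssm) {
  n <- length(seq_chars) - 34L
  if (n < 1L) return(numeric(0))
  idx <- match(seq_chars, colnames(pssm))
  idx[is.na(idx)] <- 1L  # unknown letters score as an arbitrary residue
  scores <- numeric(n)
  for (j in seq_len(35L)) {
    scores <- scores + pssm[cbind(j, idx[j:(j + n - 1L)])]
  }
  scores
}

#' Detect tandem PPR repeat arrays in a protein sequence
#'
#' Scores every 35-residue window against the repeat PSSM; windows above
#' `threshold_frac` of the maximum attainable score are candidate repeats,
#' which are greedily chained (best-scoring seed first, extending in both
#' directions at spacing 35 +/- `spacing_tol`). Arrays of fewer than two
#' repeats are discarded, matching the defining 2-30 tandem range of the
#' family.
#'
#' @param seq protein sequence (uppercase one-letter string)
#' @param pssm from [build_repeat_pssm()]
#' @param threshold_frac candidate threshold as a fraction of the maximum
#'   attainable window score (default 0.6)
#' @param spacing_tol allowed deviation from 35-residue spacing when
#'   chaining (default 1; designed constructs hit exactly 35)
#' @param protein_id identifier carried into the result
#' @return list of `ppr_repeat_array` objects, each with a `hits` data
#'   frame (`start`, `score`, `code5`, `code35`); sequences shorter than
#'   35 residues yield an empty list
#' @export
scan_protein <- function(seq, pssm, threshold_frac = 0.6, spacing_tol = 1L,
                         protein_id = "protein") {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  scores <- .window_scores(chars, pssm)
  if (!length(scores)) return(list())
  thr <- threshold_frac * attr(pssm, "max_score")
  cand <- which(scores >= thr)
  if (!length(cand)) return(list())
  used <- rep(FALSE, length(cand))
  arrays <- list()
  repeat {
    open <- which(!used)
    if (!length(open)) break
    seed <- open[which.max(scores[cand[open]])]
    chain <- cand[seed]
    used[seed] <- TRUE
    # extend right then left at spacing 35 +/- tol, best candidate per step
    for (dir in c(1L, -1L)) {
      cur <- if (dir == 1L) max(chain) else min(chain)
      repeat {
        lo <- cur + dir * 35L - spacing_tol
        hi <- cur + dir * 35L + spacing_tol
        nxt <- which(!used & cand >= lo & cand <= hi)
        if (!length(nxt)) break
        pick <- nxt[which.max(scores[cand[nxt]])]
        cur <- cand[pick]
        chain <- c(chain, cur)
        used[pick] <- TRUE
      }
    }
    chain <- sort(chain)
    # retire candidates overlapping the chained repeats so they cannot
    # seed spurious shifted arrays
    for (s in chain) used[cand > s - 35L & cand < s + 35L] <- TRUE
    if (length(chain) >= 2L) {
      hits <- data.frame(
        start = chain,
        score = scores[chain],
        code5 = chars[chain + 4L],
        code35 = chars[chain + 34L],
        stringsAsFactors = FALSE
      )
      arrays[[length(arrays) + 1L]] <-
        structure(list(hits = hits, protein_id = protein_id),
                  class = "ppr_repeat_array")
    }
  }
  arrays[order(vapply(arrays, function(a) a$hits$start[1], numeric(1)))]
}

#' @export
print.ppr_repeat_array <- function(x, ...) {
  cat("<PPR repeat array>", x$protein_id, "-", nrow(x$hits), "repeats at",
      paste(x$hits$start, collapse = ","), "\n")
  invisible(x)
}

#' Predict the RNA target of a repeat array
#'
#' Row i of the returned position probability matrix is the base profile
#' of repeat i's (5,35) code; N-to-C repeat order corresponds to 5'-to-3'
#' RNA order.
#'
#' @param array a `ppr_repeat_array` from [scan_protein()]
#' @param table a `ppr_code_table`
#' @param background background base profile (default uniform)
#' @return a `target_ppm`: an n x 4 probability matrix (columns A,C,G,U)
#'   with attributes `background` and `codes`
#' @export
predict_target <- function(array, table = default_code_table(),
                           background = base_profile(0.25, 0.25, 0.25, 0.25)) {
  stopifnot(inherits(array, "ppr_repeat_array"))
  codes <- paste0(array$hits$code5, array$hits$code35)
  rows <- t(vapply(codes, function(cd) {
    as.numeric(code_to_profile(as_ppr_code(cd), table))
  }, numeric(4)))
  colnames(rows) <- RNA_BASES
  rownames(rows) <- NULL
  structure(rows, background = as.numeric(background), codes = codes,
            class = c("target_ppm", "matrix"))
}

#' Consensus sequence of a target PPM
#'
#' @param ppm a `target_ppm`
#' @param tol probabilities within `tol` of the row maximum are tied; ties
#'   are reported with IUPAC-style brackets unless `collapse_ties`
#' @param collapse_ties if TRUE, ties resolve to the first base in A,C,G,U
#'   order
#' @return consensus string, 5' to 3'
#' @export
ppm_consensus <- function(ppm, tol = 1e-9, collapse_ties = FALSE) {
  out <- apply(unclass(ppm), 1, function(row) {
    best <- RNA_BASES[row >= max(row) - tol]
    if (length(best) == 1L || collapse_ties) best[1]
    else paste0("[", paste(best, collapse = "/"), "]")
  })
  paste(out, collapse = "")
}

#' Scan transcripts for candidate binding sites
#'
#' Every sense-strand window of each transcript is scored as
#' sum over positions of log2(p_row(base) / background(base)); PPR arrays
#' bind single-stranded RNA so the reverse complement is never scanned.
#' Ties rank by transcript order, then position. Optional empirical
#' p-values come from seeded mononucleotide shuffles of each transcript:
#' the p-value of a hit is the fraction of shuffles whose best window
#' score matches or beats it (with the usual +1 correction).
#'
#' @param ppm a `target_ppm`
#' @param transcripts named character vector of RNA/DNA sequences (T is
#'   treated as U), or a path to a FASTA file
#' @param top_k number of hits to return (0 gives an empty table)
#' @param null_shuffles number of mononucleotide shuffles per transcript
#'   for empirical p-values (0 skips them)
#' @param seed RNG seed for the shuffles
#' @return data frame of class `site_hits`: `transcript_id`, `start`
#'   (1-based), `score` (bits), `site`, and `p_empirical` when requested.
#'   Transcripts shorter than the site are skipped with a warning.
#' @export
scan_transcripts <- function(ppm, transcripts, top_k = 10L, null_shuffles = 0L,
                             seed = NULL) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      is.null(names(transcripts)) && file.exists(transcripts)) {
    transcripts <- read_fasta(transcripts, type = "rna")
  }
  if (is.null(names(transcripts))) {
    names(transcripts) <- paste0("tx", seq_along(transcripts))
  }
  w <- nrow(ppm)
  bg <- attr(ppm, "background")
  lodds <- log2(unclass(ppm) / matrix(bg, nrow = w, ncol = 4, byrow = TRUE))
  score_tx <- function(chars) {
    n <- length(chars) - w + 1L
    idx <- match(chars, RNA_BASES)
    s <- numeric(n)
    for (j in seq_len(w)) s <- s + lodds[cbind(j, idx[j:(j + n - 1L)])]
    s
  }
  all_hits <- list()
  maxima <- list()
  if (!is.null(seed)) set.seed(seed)
  for (k in seq_along(transcripts)) {
    chars <- strsplit(toupper(transcripts[[k]]), "")[[1]]
    chars[chars == "T"] <- "U"
    if (length(chars) < w) {
      warning("transcript '", names(transcripts)[k],
              "' is shorter than the ", w, "-nt site; skipped", call. = FALSE)
      next
    }
    s <- score_tx(chars)
    all_hits[[length(all_hits) + 1L]] <- data.frame(
      transcript_id = names(transcripts)[k],
      tx_order = k,
      start = seq_along(s),
      score = s,
      site = vapply(seq_along(s), function(i) {
        paste(chars[i:(i + w - 1L)], collapse = "")
      }, character(1)),
      stringsAsFactors = FALSE
    )
    if (null_shuffles > 0L) {
      maxima[[names(transcripts)[k]]] <- vapply(seq_len(null_shuffles),
        function(r) max(score_tx(sample(chars))), numeric(1))
    }
  }
  if (!length(all_hits)) {
    return(structure(data.frame(transcript_id = character(0),
                                start = integer(0), score = numeric(0),
                                site = character(0)), class = c("site_hits", "data.frame")))
  }
  hits <- do.call(rbind, all_hits)
  hits <- hits[order(-hits$score, hits$tx_order, hits$start), , drop = FALSE]
  hits$tx_order <- NULL
  hits <- utils::head(hits, max(0L, top_k))
  rownames(hits) <- NULL
  if (null_shuffles > 0L && nrow(hits)) {
    hits$p_empirical <- vapply(seq_len(nrow(hits)), function(i) {
      nulls <- maxima[[hits$transcript_id[i]]]
      (sum(nulls >= hits$score[i]) + 1) / (length(nulls) + 1)
    }, numeric(1))
  }
  structure(hits, class = c("site_hits", "data.frame"))
}
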