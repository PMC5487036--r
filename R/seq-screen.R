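# Sequence-level candidate screening: pairwise identity and average mass.

#' Parameters for pairwise identity computation
#'
#' Global (Needleman-Wunsch) alignment parameters. The identity
#' denominator is either the alignment length including internal gaps but
#' excluding terminal overhangs (default, the convention echoed in every
#' report) or the shorter sequence length.
#'
#' @param substitution Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @param denominator `"alignment_length"` or `"shorter_sequence"`.
#' @return List of class `cna_identity_params`.
#' @export
identity_params <- function(substitution = "BLOSUM62", gap_open = 10,
                            gap_extend = 0.5,
                            denominator = c("alignment_length",
                                            "shorter_sequence")) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  denominator <- match.arg(denominator)
  structure(list(substitution = substitution, gap_open = gap_open,
                 gap_extend = gap_extend, denominator = denominator),
            class = "cna_identity_params")
}

#' Percent sequence identity from a global pairwise alignment
#'
#' Aligns two amino-acid sequences with the Needleman-Wunsch algorithm
#' and returns `100 * identical columns / denominator`. Symmetric in its
#' two arguments.
#'
#' @param a,b Amino-acid sequences (character strings).
#' @param params An [identity_params()] list.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, params = identity_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = params$substitution,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- pa == "-" | pb == "-"
  # trim terminal gap overhangs
  core <- which(!gap)
  if (length(core) == 0) return(0)
  keep <- seq(min(core), max(core))
  pa <- pa[keep]; pb <- pb[keep]
  ident <- sum(pa == pb & pa != "-")
  denom <- switch(params$denominator,
                  alignment_length = length(pa),
                  shorter_sequence = min(nchar(a), nchar(b)))
  100 * ident / denom
}

#' Screen candidate sequences for mutual low identity
#'
#' Computes all pairwise identities and flags each pair as passing when
#' its identity is strictly below `threshold` (the candidate-selection
#' criterion: divergent domains only).
#'
#' @param seqs Named character vector of amino-acid sequences (>= 2,
#'   unique names).
#' @param threshold Percent identity cutoff (default 30).
#' @param params An [identity_params()] list.
#' @return List with `matrix` (symmetric percent-identity matrix,
#'   diagonal 100), `pairs` (tibble: `a`, `b`, `identity`, `pass`),
#'   `all_pass`, and the parameters used.
#' @export
screen_candidates <- function(seqs, threshold = 30,
                              params = identity_params()) {
  if (length(seqs) < 2) stop("need at least two sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must carry unique names")
  }
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      pid <- pairwise_identity(seqs[[i]], seqs[[j]], params)
      m[i, j] <- m[j, i] <- pid
      pairs[[length(pairs) + 1]] <- tibble::tibble(
        a = names(seqs)[i], b = names(seqs)[j],
        identity = pid, pass = pid < threshold)
    }
  }
  pairs <- dplyr::bind_rows(pairs)
  list(matrix = m, pairs = pairs, all_pass = all(pairs$pass),
       threshold = threshold, params = params)
}

# average residue masses (Da), standard atomic weights
AA_RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_MASS <- 18.0153

#' Average molecular mass of a protein sequence
#'
#' Sum of average residue masses plus one water, in Dalton. Average (not
#' monoisotopic) masses are used, matching gel-based size estimates.
#'
#' @param seq Amino-acid sequence (standard 20 letters).
#' @return Mass in Da.
#' @export
compute_mass <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  letters1 <- strsplit(toupper(seq), "")[[1]]
  unknown <- setdiff(letters1, names(AA_RESIDUE_MASS))
  if (length(unknown) > 0) {
    stop("unknown amino-acid letter(s): ", paste(unknown, collapse = ", "))
  }
  sum(AA_RESIDUE_MASS[letters1]) + WATER_MASS
}
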