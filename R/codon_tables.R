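# Nei-Gojobori (1986) codon machinery: site fractions, pathway-averaged
# substitution classification, and per-codon mutational opportunity lists.
#
# Conventions pinned here (and documented in the methods vignette):
#   * standard genetic code (bacterial code with starts simplified to ATG);
#   * each codon position carries up to 1 site of weight, split 1/3 per
#     possible single-nucleotide change; changes producing stop codons are
#     excluded and their 1/3 weight removed from both S and N, so
#     s + n <= 3 with equality iff no neighbor is a stop;
#   * substitution pathways passing through stop codons are excluded; when
#     every pathway is excluded the differences are classified by direct
#     per-position substitution and the pair is flagged.

NT <- c("A", "C", "G", "T")

CODONS <- as.vector(outer(outer(NT, NT, paste0), NT, paste0))
CODONS <- sort(CODONS)  # index = base-4 rank with A<C<G<T

codon_index <- function(codons) {
  i <- match(codons, CODONS)
  if (anyNA(i)) {
    bad <- unique(codons[is.na(i)])
    stopf("not a codon over {A,C,G,T}: %s", paste(head(bad, 3), collapse = ", "))
  }
  i
}

CODON_AA <- {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[CODONS])
}
IS_STOP <- CODON_AA == "*"
STOP_CODONS <- CODONS[IS_STOP]

# Single-nucleotide neighbor of a codon: change `pos` to `alt`.
codon_neighbor <- function(codon, pos, alt) {
  substr(codon, pos, pos) <- alt
  codon
}

# --- site fractions and mutational opportunity lists -------------------------

.build_codon_tables <- function() {
  s_sites <- n_sites <- rep(NA_real_, 64L)
  empty <- matrix(integer(), 0, 3)
  syn_changes <- nonsyn_changes <- rep(list(empty), 64L)
  for (i in seq_len(64L)) {
    if (IS_STOP[i]) next
    codon <- CODONS[i]
    s <- 0; n <- 0
    syn <- list(); non <- list()
    for (pos in 1:3) {
      ref_nt <- substr(codon, pos, pos)
      for (alt in setdiff(NT, ref_nt)) {
        nb <- codon_neighbor(codon, pos, alt)
        j <- match(nb, CODONS)
        if (IS_STOP[j]) next  # excluded: weight removed from both S and N
        if (CODON_AA[j] == CODON_AA[i]) {
          s <- s + 1 / 3
          syn[[length(syn) + 1L]] <- c(pos, match(alt, NT), j)
        } else {
          n <- n + 1 / 3
          non[[length(non) + 1L]] <- c(pos, match(alt, NT), j)
        }
      }
    }
    s_sites[i] <- s
    n_sites[i] <- n
    syn_changes[[i]] <- if (length(syn)) do.call(rbind, syn) else
      matrix(integer(), 0, 3)
    nonsyn_changes[[i]] <- if (length(non)) do.call(rbind, non) else
      matrix(integer(), 0, 3)
  }
  list(s = s_sites, n = n_sites, syn = syn_changes, nonsyn = nonsyn_changes)
}

.CT <- .build_codon_tables()
S_SITES <- .CT$s
N_SITES <- .CT$n
SYN_CHANGES <- .CT$syn       # per codon: matrix(pos, alt-nt index, new codon index)
NONSYN_CHANGES <- .CT$nonsyn
SYN_N <- vapply(SYN_CHANGES, nrow, integer(1))       # mutational opportunity
NONSYN_N <- vapply(NONSYN_CHANGES, nrow, integer(1))
rm(.CT)

# --- pathway-averaged substitution counting ----------------------------------

.PERMS <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# Classify one ordered pathway from codon a to codon b over `diff_pos`.
# Returns NULL if an intermediate (or terminal step result) is a stop codon,
# else list(sd, nd, per-position syn indicator).
.walk_pathway <- function(codon_a, codon_b, order_pos) {
  cur <- codon_a
  sd <- 0; nd <- 0
  pos_syn <- rep(NA_real_, 3L)
  for (pos in order_pos) {
    nxt <- codon_neighbor(cur, pos, substr(codon_b, pos, pos))
    if (Biostrings::GENETIC_CODE[[nxt]] == "*") return(NULL)
    syn <- Biostrings::GENETIC_CODE[[nxt]] == Biostrings::GENETIC_CODE[[cur]]
    if (syn) sd <- sd + 1 else nd <- nd + 1
    pos_syn[pos] <- as.numeric(syn)
    cur <- nxt
  }
  list(sd = sd, nd = nd, pos_syn = pos_syn)
}

.build_pair_tables <- function() {
  SD <- ND <- matrix(NA_real_, 64L, 64L)
  BLOCKED <- matrix(FALSE, 64L, 64L)
  W <- array(NA_real_, c(64L, 64L, 3L))  # per-position synonymous weight
  for (i in seq_len(64L)) {
    if (IS_STOP[i]) next
    ca <- CODONS[i]
    for (j in seq_len(64L)) {
      if (IS_STOP[j]) next
      cb <- CODONS[j]
      dp <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
      d <- length(dp)
      if (d == 0L) { SD[i, j] <- 0; ND[i, j] <- 0; next }
      paths <- lapply(.PERMS[[as.character(d)]],
                      function(p) .walk_pathway(ca, cb, dp[p]))
      paths <- Filter(Negate(is.null), paths)
      if (length(paths) == 0L) {
        # all pathways pass through stops: direct per-position classification
        BLOCKED[i, j] <- TRUE
        sd <- 0; nd <- 0
        for (pos in dp) {
          nb <- codon_neighbor(ca, pos, substr(cb, pos, pos))
          syn <- !IS_STOP[match(nb, CODONS)] &&
            CODON_AA[match(nb, CODONS)] == CODON_AA[i]
          if (syn) { sd <- sd + 1; W[i, j, pos] <- 1 }
          else     { nd <- nd + 1; W[i, j, pos] <- 0 }
        }
        SD[i, j] <- sd; ND[i, j] <- nd
      } else {
        SD[i, j] <- mean(vapply(paths, `[[`, numeric(1), "sd"))
        ND[i, j] <- mean(vapply(paths, `[[`, numeric(1), "nd"))
        for (pos in dp) {
          W[i, j, pos] <- mean(vapply(paths, function(p) p$pos_syn[pos],
                                      numeric(1)))
        }
      }
    }
  }
  list(SD = SD, ND = ND, BLOCKED = BLOCKED, W = W)
}

.PT <- .build_pair_tables()
SD_MAT <- .PT$SD
ND_MAT <- .PT$ND
BLOCKED_MAT <- .PT$BLOCKED
SYNW_ARR <- .PT$W
rm(.PT)

# Positions differing between codon pairs: SYNW_ARR carries a (possibly 0)
# weight exactly at differing positions of sense-codon pairs.
NDIFF_MAT <- apply(!is.na(SYNW_ARR), c(1, 2), sum)

#' Nei-Gojobori synonymous and nonsynonymous site counts for one codon
#'
#' Each of a codon's 9 single-nucleotide neighbors is classified as
#' synonymous or nonsynonymous under the standard genetic code and
#' contributes 1/3 of a site; neighbors that are stop codons are excluded
#' and their weight removed, so `s + n <= 3` with equality exactly when no
#' neighbor is a stop.
#'
#' @param codon A 3-letter codon over \{A,C,G,T\}; stop codons and codons
#'   containing N are errors.
#' @return Named numeric vector `c(s, n)`.
#' @examples
#' ng_sites("TTT")  # s = 1/3, n = 8/3
#' @export
ng_sites <- function(codon) {
  codon <- check_dna(codon, "codon")
  if (nchar(codon) != 3L) stopf("codon must have length 3")
  if (grepl("N", codon)) stopf("codon must not contain N")
  i <- codon_index(codon)
  if (IS_STOP[i]) stopf("'%s' is a stop codon", codon)
  c(s = S_SITES[i], n = N_SITES[i])
}

#' Pathway-averaged substitution counts between two codons
#'
#' Differences between two sense codons are decomposed into single-step
#' mutational pathways; each step is classified synonymous or nonsynonymous
#' and counts are averaged over all pathways with equal weight. Pathways
#' passing through a stop codon are excluded; if every pathway is excluded
#' the differences are classified by direct per-position substitution and
#' the result is flagged `blocked`.
#'
#' @param codon_a,codon_b Sense codons over \{A,C,G,T\}.
#' @return List with `sd`, `nd` (may be fractional) and logical `blocked`.
#' @examples
#' ng_substitutions("TTT", "GTA")  # sd 0.5, nd 1.5
#' @export
ng_substitutions <- function(codon_a, codon_b) {
  i <- codon_index(check_dna(codon_a, "codon_a"))
  j <- codon_index(check_dna(codon_b, "codon_b"))
  if (IS_STOP[i] || IS_STOP[j]) stopf("stop codons are not comparable")
  list(sd = SD_MAT[i, j], nd = ND_MAT[i, j], blocked = BLOCKED_MAT[i, j])
}
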