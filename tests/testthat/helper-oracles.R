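# Independent oracles used by the test suite. These deliberately share no
# code with the package: neighbor/pathway enumeration is written from the
# counting rules, and the alignment oracle is a plain quadratic-space
# affine-gap DP returning only the optimal score.

.NT <- c("A", "C", "G", "T")
.GC <- Biostrings::GENETIC_CODE

oracle_aa <- function(codon) unname(.GC[codon])
oracle_is_stop <- function(codon) oracle_aa(codon) == "*"

# site fractions: each position's three neighbor changes carry 1/3 site
# each; changes to stop codons are excluded from both S and N
oracle_ng_sites <- function(codon) {
  s <- 0; n <- 0
  for (pos in 1:3) {
    for (alt in setdiff(.NT, substr(codon, pos, pos))) {
      nb <- codon
      substr(nb, pos, pos) <- alt
      if (oracle_is_stop(nb)) next
      if (oracle_aa(nb) == oracle_aa(codon)) s <- s + 1 / 3 else n <- n + 1 / 3
    }
  }
  c(s = s, n = n)
}

# pathway-averaged substitution counts; pathways through stops dropped;
# all-blocked pairs fall back to direct per-position classification
oracle_ng_subs <- function(ca, cb) {
  dp <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (!length(dp)) return(c(sd = 0, nd = 0))
  perms <- if (length(dp) == 1) list(dp) else {
    pm <- list()
    rec <- function(prefix, rest) {
      if (!length(rest)) { pm[[length(pm) + 1]] <<- prefix; return() }
      for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
    }
    rec(integer(0), dp)
    pm
  }
  res <- list()
  for (p in perms) {
    cur <- ca; sd <- 0; nd <- 0; ok <- TRUE
    for (pos in p) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(cb, pos, pos)
      if (oracle_is_stop(nxt)) { ok <- FALSE; break }
      if (oracle_aa(nxt) == oracle_aa(cur)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) res[[length(res) + 1]] <- c(sd, nd)
  }
  if (!length(res)) {  # all pathways blocked: direct classification
    sd <- 0; nd <- 0
    for (pos in dp) {
      nb <- ca
      substr(nb, pos, pos) <- substr(cb, pos, pos)
      if (!oracle_is_stop(nb) && oracle_aa(nb) == oracle_aa(ca)) sd <- sd + 1
      else nd <- nd + 1
    }
    return(c(sd = sd, nd = nd))
  }
  m <- Reduce(`+`, res) / length(res)
  c(sd = m[1], nd = m[2])
}

sense_codons <- function() {
  all <- as.vector(outer(outer(.NT, .NT, paste0), .NT, paste0))
  all[!oracle_is_stop(all)]
}

# quadratic affine-gap global alignment score (Gotoh), gap of length k
# costs open + k * extend; N mismatches everything
oracle_align_score <- function(a, b, match = 2, mismatch = -3,
                               gap_open = -5, gap_extend = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- gap_open + (i - 1) * gap_extend
  for (j in 2:(m + 1)) Y[1, j] <- gap_open + (j - 1) * gap_extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1] && av[i - 1] != "N") match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + gap_open + gap_extend,
                     X[i - 1, j] + gap_extend,
                     Y[i - 1, j] + gap_open + gap_extend)
      Y[i, j] <- max(M[i, j - 1] + gap_open + gap_extend,
                     X[i, j - 1] + gap_open + gap_extend,
                     Y[i, j - 1] + gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_dna <- function(n) paste(sample(.NT, n, replace = TRUE), collapse = "")

# a random in-frame CDS of n_codons with ATG start, sense interior, stop end
random_cds <- function(n_codons) {
  sense <- sense_codons()
  paste(c("ATG", sample(sense, n_codons - 2, replace = TRUE),
          sample(c("TAA", "TAG", "TGA"), 1)), collapse = "")
}
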