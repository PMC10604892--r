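# Independent oracles used by the property-style tests. These re-derive
# expected results by brute force or exhaustive enumeration, using code
# paths (regex matching, seqinr translation, phangorn least-squares
# topology fitting) that are separate from the package implementation.

# ---- zinc-finger scaffold oracle -------------------------------------

# Enumerate every (start, cys-spacer a, his-spacer b) substring that
# satisfies the scaffold grammar, via anchored regexes on the exact-length
# substring; then apply the documented selection rule (leftmost start,
# smallest a then b, non-overlapping left to right).
oracle_scan <- function(seq, cys_spacer = c(2, 4), his_spacer = c(3, 5),
                        hexapeptides = c("QALGGH", "KSLGGH", "KALGGH",
                                         "RSLGGH", "RALGGH")) {
  L <- nchar(seq)
  cands <- list()
  for (s in seq_len(L)) {
    for (a in cys_spacer[1]:cys_spacer[2]) {
      for (b in his_spacer[1]:his_spacer[2]) {
        len <- 16 + a + b
        if (s + len - 1 > L) next
        sub <- substr(seq, s, s + len - 1)
        re <- sprintf("^C.{%d}C.{3}F.{3}(%s).{%d}H$", a,
                      paste(hexapeptides, collapse = "|"), b)
        if (grepl(re, sub, perl = TRUE)) {
          hex <- substr(sub, 1 + a + 1 + 3 + 1 + 3 + 1,
                        1 + a + 1 + 3 + 1 + 3 + 6)
          cands[[length(cands) + 1]] <- data.frame(
            start = s, end = s + len - 1, a = a, b = b,
            hexapeptide = hex, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(cands) == 0) {
    return(data.frame(start = integer(), end = integer(), a = integer(),
                      b = integer(), hexapeptide = character()))
  }
  cands <- do.call(rbind, cands)
  cands <- cands[order(cands$start, cands$a, cands$b), ]
  chosen <- list()
  cursor <- 1
  while (TRUE) {
    ok <- cands[cands$start >= cursor, , drop = FALSE]
    if (nrow(ok) == 0) break
    pick <- ok[1, ]
    chosen[[length(chosen) + 1]] <- pick
    cursor <- pick$end + 1
  }
  do.call(rbind, chosen)
}

# ---- Nei-Gojobori oracle ---------------------------------------------

oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

oracle_is_stop <- function(codon) oracle_translate(codon) == "*"

oracle_syn_sites_codon <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    alts <- setdiff(c("A", "C", "G", "T"), chars[pos])
    syn <- 0
    valid <- 0
    for (nt in alts) {
      alt <- chars
      alt[pos] <- nt
      altc <- paste(alt, collapse = "")
      if (oracle_is_stop(altc)) next
      valid <- valid + 1
      if (oracle_translate(altc) == oracle_translate(codon)) syn <- syn + 1
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

oracle_perms <- list(
  list(1),
  list(c(1, 2), c(2, 1)),
  list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
       c(3, 2, 1))
)

oracle_codon_diffs <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  dp <- which(a != b)
  if (length(dp) == 0) return(c(0, 0))
  results <- list()
  for (ord in oracle_perms[[length(dp)]]) {
    cur <- a
    syn <- 0
    nonsyn <- 0
    blocked <- FALSE
    for (step in ord) {
      nxt <- cur
      nxt[dp[step]] <- b[dp[step]]
      if (oracle_is_stop(paste(nxt, collapse = ""))) {
        blocked <- TRUE
        break
      }
      if (oracle_translate(paste(cur, collapse = "")) ==
          oracle_translate(paste(nxt, collapse = ""))) {
        syn <- syn + 1
      } else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    if (!blocked) results[[length(results) + 1]] <- c(syn, nonsyn)
  }
  if (length(results) == 0) {
    # all pathways blocked: average over all, ignoring stop exclusion
    for (ord in oracle_perms[[length(dp)]]) {
      cur <- a
      syn <- 0
      nonsyn <- 0
      for (step in ord) {
        nxt <- cur
        nxt[dp[step]] <- b[dp[step]]
        if (oracle_translate(paste(cur, collapse = "")) ==
            oracle_translate(paste(nxt, collapse = ""))) {
          syn <- syn + 1
        } else nonsyn <- nonsyn + 1
        cur <- nxt
      }
      results[[length(results) + 1]] <- c(syn, nonsyn)
    }
  }
  Reduce(`+`, results) / length(results)
}

oracle_nei_gojobori <- function(cds_a, cds_b) {
  ca <- substring(cds_a, seq(1, nchar(cds_a), 3), seq(3, nchar(cds_a), 3))
  cb <- substring(cds_b, seq(1, nchar(cds_b), 3), seq(3, nchar(cds_b), 3))
  S <- (sum(vapply(ca, oracle_syn_sites_codon, numeric(1))) +
          sum(vapply(cb, oracle_syn_sites_codon, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  d <- vapply(seq_along(ca), function(i) oracle_codon_diffs(ca[i], cb[i]),
              numeric(2))
  Sd <- sum(d[1, ])
  Nd <- sum(d[2, ])
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, Ks = jc(Sd / S), Ka = jc(Nd / N))
}

# random sense codon string without internal stops
random_cds <- function(n_codons) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# ---- neighbor-joining oracle -----------------------------------------

# random additive distance matrix from a random unrooted tree
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.1, 1))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# exhaustive-topology least-squares oracle: the generating topology of an
# additive matrix is the unique one with (near) zero least-squares
# residual among all unrooted topologies
oracle_best_topology <- function(d) {
  labels <- rownames(d)
  all_t <- phangorn::allTrees(length(labels), rooted = FALSE,
                              tip.label = labels)
  resid <- vapply(all_t, function(t) {
    fit <- phangorn::nnls.tree(d, t, method = "unrooted")
    sum((ape::cophenetic.phylo(fit)[labels, labels] - d)^2)
  }, numeric(1))
  all_t[[which.min(resid)]]
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
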