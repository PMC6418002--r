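# Independent brute-force oracles used to check the package's estimators.
# These deliberately re-derive each quantity from first principles rather
# than calling the implementation under test.

# ---- pan/core oracle: explicit set arithmetic ------------------------------

oracle_curve <- function(sets) {
  G <- length(sets)
  out <- list()
  for (g in seq_len(G)) {
    for (combo in utils::combn(G, g, simplify = FALSE)) {
      u <- Reduce(union, sets[combo])
      i <- Reduce(intersect, sets[combo])
      out[[length(out) + 1L]] <- data.frame(g = g, pan = length(u),
                                            core = length(i))
    }
  }
  do.call(rbind, out)
}

presence_from_sets <- function(sets) {
  all_cl <- sort(unique(unlist(sets)))
  m <- vapply(sets, function(s) all_cl %in% s, logical(length(all_cl)))
  rownames(m) <- all_cl
  m
}

# ---- MRCA oracle: root-to-leaf path intersection ---------------------------

oracle_mrca <- function(phy, leaves) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  path <- function(tip) {
    n <- match(tip, phy$tip.label)
    p <- n
    while (n != root) {
      n <- phy$edge[phy$edge[, 2] == n, 1]
      p <- c(p, n)
    }
    p
  }
  shared <- Reduce(intersect, lapply(leaves, path))
  phy$node.label[shared[1] - ntip]   # paths ordered tip -> root
}

# ---- NG86 oracles: neighbor and pathway enumeration ------------------------

oracle_code <- as.character(Biostrings::GENETIC_CODE)
names(oracle_code) <- names(Biostrings::GENETIC_CODE)
oracle_stops <- names(oracle_code)[oracle_code == "*"]
oracle_sense <- setdiff(names(oracle_code), oracle_stops)

oracle_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    neigh <- vapply(setdiff(c("A", "C", "G", "T"), ch[pos]), function(b) {
      x <- ch; x[pos] <- b; paste(x, collapse = "")
    }, character(1))
    neigh <- neigh[!neigh %in% oracle_stops]
    if (length(neigh) > 0) {
      s <- s + mean(oracle_code[neigh] == oracle_code[[codon]])
    }
  }
  c(S = s, N = 3 - s)
}

# every ordering of the differing positions, as a recursion over lists
oracle_orderings <- function(pos) {
  if (length(pos) <= 1L) return(list(pos))
  res <- list()
  for (p in pos) {
    for (rest in oracle_orderings(setdiff(pos, p))) {
      res[[length(res) + 1L]] <- c(p, rest)
    }
  }
  res
}

oracle_diffs <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  pos <- which(ca != cb)
  if (length(pos) == 0L) return(c(S = 0, N = 0))
  counts <- list()
  for (ord in oracle_orderings(pos)) {
    cur <- ca; s <- 0; n <- 0; valid <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- cb[p]
      if (paste(nxt, collapse = "") %in% oracle_stops) { valid <- FALSE; break }
      if (oracle_code[[paste(cur, collapse = "")]] ==
          oracle_code[[paste(nxt, collapse = "")]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (valid) counts[[length(counts) + 1L]] <- c(s, n)
  }
  m <- colMeans(do.call(rbind, counts))
  c(S = m[1], N = m[2])
}
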