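# Independent oracles, written against the definitions (not the package
# internals) and kept deliberately naive.

# all-pairs heavy-atom contact computation: double loop, explicit sqrt
oracle_contact_edges <- function(complex, threshold = 4.5) {
  chains <- list(complex$interactor, complex$partner)
  atoms <- c(chains[[1]]$atoms, chains[[2]]$atoms)
  n <- length(atoms)
  edges <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      hit <- FALSE
      ai <- atoms[[i]]; aj <- atoms[[j]]
      for (a in seq_len(nrow(ai))) {
        for (b in seq_len(nrow(aj))) {
          if (sqrt(sum((ai[a, ] - aj[b, ])^2)) <= threshold) { hit <- TRUE; break }
        }
        if (hit) break
      }
      if (hit) edges <- rbind(edges, c(i, j))
    }
  }
  edges
}

# interface nodes by scanning edges against chain roles
oracle_interface <- function(graph) {
  role <- graph$nodes$chain_role
  out <- integer(0)
  for (e in seq_len(nrow(graph$edges))) {
    a <- graph$edges[e, 1]; b <- graph$edges[e, 2]
    if (role[a] != role[b]) out <- c(out, a, b)
  }
  sort(unique(out))
}

# O(n^2) AUC: concordant pairs count 1, ties 1/2
oracle_auc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# connected components of the pairwise-identity >= threshold graph
oracle_identity_components <- function(seqs, threshold = 0.5) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  ident <- function(a, b) {
    m <- min(nchar(a), nchar(b))
    va <- strsplit(substr(a, 1, m), "")[[1]]
    vb <- strsplit(substr(b, 1, m), "")[[1]]
    sum(va == vb) / m
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (ident(seqs[i], seqs[j]) >= threshold) {
      parent[find(i)] <- find(j)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# random residue cloud (1-3 heavy atoms per residue in a box)
random_chain <- function(chain_id, n_res, box = 18, seed = 1) {
  set.seed(seed)
  atoms <- lapply(seq_len(n_res), function(j) {
    k <- sample(1:3, 1)
    m <- matrix(runif(3 * k, 0, box), k, 3)
    colnames(m) <- c("x", "y", "z")
    rownames(m) <- rep("C", k)
    m
  })
  chain_structure(chain_id, sample(c("A", "G", "L", "K"), n_res, replace = TRUE), atoms)
}
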