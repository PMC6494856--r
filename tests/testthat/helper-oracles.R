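## Independent brute-force oracles and small fixture builders shared by the
## tests.  These deliberately avoid the package's own code paths.

## Bray-Curtis by explicit double loop over sample pairs.
bc_brute <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (a in seq_len(n)) for (b in seq_len(n))
    d[a, b] <- sum(abs(m[a, ] - m[b, ])) / sum(m[a, ] + m[b, ])
  d
}

## SIMPER per-OTU contributions by explicit triple loop.
simper_brute <- function(m, ia, ib) {
  contrib <- numeric(ncol(m))
  for (a in ia) for (b in ib) {
    denom <- sum(m[a, ] + m[b, ])
    for (i in seq_len(ncol(m)))
      contrib[i] <- contrib[i] + abs(m[a, i] - m[b, i]) / denom
  }
  contrib / (length(ia) * length(ib))
}

## Exhaustive modularity maximum by recursive best-bipartition refinement
## (feasible for n <= 10).
brute_modularity_max <- function(w) {
  part <- rep(1L, nrow(w))
  q <- coralnet::modularity_q(w, part)
  repeat {
    best <- q; best_part <- part
    for (mod in unique(part)) {
      idx <- which(part == mod)
      k <- length(idx)
      if (k < 2) next
      for (code in 1:(2^(k - 1) - 1)) {
        bits <- as.integer(intToBits(code))[1:k]
        cand <- part
        cand[idx[bits == 1]] <- max(part) + 1L
        qc <- coralnet::modularity_q(w, cand)
        if (qc > best + 1e-12) { best <- qc; best_part <- cand }
      }
    }
    if (best <= q + 1e-12) break
    q <- best; part <- best_part
  }
  q
}

## Random small count table with unique ids.
random_counts <- function(n = 5, p = 4, max_count = 20) {
  m <- matrix(sample.int(max_count, n * p, replace = TRUE), n, p,
              dimnames = list(paste0("s", seq_len(n)), paste0("o", seq_len(p))))
  m
}

## Weighted two-block graph: in-block weight 1, cross-block weight `cross`.
planted_block_graph <- function(sizes, cross = 0.05) {
  blk <- rep(seq_along(sizes), sizes)
  n <- length(blk)
  w <- matrix(cross, n, n)
  w[outer(blk, blk, "==")] <- 1
  diag(w) <- 0
  dimnames(w) <- list(paste0("s", 1:n), paste0("s", 1:n))
  list(w = w, blocks = blk)
}

## Two disconnected triangles (unweighted).
two_triangles <- function() {
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- 1; w[4:6, 4:6] <- 1
  diag(w) <- 0
  dimnames(w) <- list(paste0("s", 1:6), paste0("s", 1:6))
  w
}

## Balanced metadata frame matching the emulated survey design: 3 genera,
## 2 species each, 4 sites, 3 times, one colony per species x site cell.
survey_design <- function() {
  sp <- c("Pa", "Pb", "Aa", "Ab", "Da", "Db")
  gn <- rep(c("P", "A", "D"), each = 2)
  df <- expand.grid(species = sp, site = c("s1", "s2", "s3", "s4"),
                    time = c("t1", "t2", "t3"), stringsAsFactors = FALSE)
  df$genus <- gn[match(df$species, sp)]
  rownames(df) <- paste0("smp", seq_len(nrow(df)))
  df
}
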