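# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition, by enumeration or quadratic
# search, and share no code with the implementation under test.

# BH from the definition: q_i = min_{j : p_(j) >= p_(i)} p_(j) * n / rank(j),
# computed as the step-up running minimum over the sorted p-values.
bh_brute_force <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    q_sorted[i] <- min(vapply(i:n, function(j) p[o[j]] * n / j, numeric(1)), 1)
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# All permutations of 1..n built by filtering the full n^n tuple grid.
perm_grid <- function(n) {
  g <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  g[apply(g, 1, function(r) length(unique(r)) == n), , drop = FALSE]
}

# Two-sided exhaustive-permutation Spearman p-value from first principles.
spearman_perm_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perms <- perm_grid(length(x))
  stats <- apply(perms, 1, function(idx) abs(cor(rx, ry[idx])))
  mean(stats >= obs - 1e-12)
}

# Quadratic all-pairs candidate search from the overlap definition.
candidate_pairs_oracle <- function(enhancers, gene_ids, annotations, cfg) {
  genes <- annotations[annotations$id %in% gene_ids, ]
  out <- list()
  for (i in seq_len(nrow(enhancers))) {
    ctr <- floor((enhancers$start[i] + enhancers$end[i]) / 2)
    ws <- max(ctr - cfg$link_window, 0); we <- ctr + cfg$link_window
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != enhancers$chrom[i]) next
      if (genes$strand[j] == "+") {
        ps <- genes$tss[j] - cfg$promoter_upstream
        pe <- genes$tss[j] + cfg$promoter_downstream
      } else {
        ps <- genes$tss[j] - cfg$promoter_downstream
        pe <- genes$tss[j] + cfg$promoter_upstream
      }
      ps <- max(ps, 0)
      if (ws < pe && ps < we) {
        out[[length(out) + 1]] <- data.frame(
          enhancer_id = enhancers$id[i], gene_id = genes$id[j],
          distance = abs(genes$tss[j] - ctr), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(enhancer_id = character(), gene_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$enhancer_id, res$distance, res$gene_id), ]
  rownames(res) <- NULL
  res
}

# Quadratic SNP-to-extended-enhancer mapping oracle.
map_snps_oracle <- function(snps, enhancers, cfg) {
  out <- list()
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(enhancers))) {
      s <- max(enhancers$start[j] - cfg$snp_flank, 0)
      e <- enhancers$end[j] + cfg$snp_flank
      if (snps$chrom[i] == enhancers$chrom[j] &&
          snps$pos0[i] >= s && snps$pos0[i] < e) {
        out[[length(out) + 1]] <- c(snps$rs_id[i], enhancers$id[j])
      }
    }
  }
  if (!length(out)) return(character())
  sort(vapply(out, paste, "", collapse = "|"))
}

# Hypergeometric upper tail by enumerating every size-n draw (combn).
hypergeom_enum_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)     # first K universe elements form the set
  mean(hits >= k)
}

# Exhaustive single-window PWM score tail over all 4^L windows.
pwm_tail_oracle <- function(pwm, s) {
  L <- nrow(pwm$probs)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  lo <- log2(sweep(pwm$probs, 2, pwm$background, "/"))
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    sum(lo[cbind(seq_len(L), grid[i, ])])
  }, numeric(1))
  probs <- vapply(seq_len(nrow(grid)), function(i) {
    prod(pwm$background[grid[i, ]])
  }, numeric(1))
  vapply(s, function(si) sum(probs[scores >= si - 1e-9]), numeric(1))
}
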