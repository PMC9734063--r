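# Shared fixture builders and independent oracles. Oracles are written
# from the definitions (enumeration / closed forms), independent of the
# package's code paths.

tiny_count_matrix <- function(counts, conditions, region = "R01") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("f%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  meta <- data.frame(sample = colnames(counts), region = region,
                     condition = conditions,
                     replicate = stats::ave(seq_along(conditions),
                                            conditions, FUN = seq_along),
                     stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}

with_seed_helper <- function(seed, expr) {
  set.seed(seed)
  force(expr)
}

# hypergeometric upper tail P(X >= k) by direct summation of the pmf
oracle_hyper_tail <- function(k, K, N, n) {
  lo <- max(0, n + K - N); hi <- min(n, K)
  if (k > hi) return(0)
  i <- max(k, lo):hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# binomial upper tail P(X >= k) by direct summation
oracle_binom_tail <- function(k, n, p0) {
  if (k <= 0) return(1)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p0) + (n - i) * log1p(-p0)))
}

# BH step-up from the definition: q_i = min_{j: p_(j) >= p_(i)} m p_(j)/j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  run_min <- Inf
  for (j in m:1) {
    run_min <- min(run_min, m * p[o[j]] / j)
    q_sorted[j] <- min(run_min, 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# exact two-sided rank-sum p by recursive enumeration of group
# assignments (independent of the combn-based implementation)
oracle_rank_sum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  sums <- c()
  rec <- function(start, left, acc) {
    if (left == 0) { sums <<- c(sums, acc); return(invisible()) }
    for (i in start:(n - left + 1)) rec(i + 1, left - 1, acc + r[i])
  }
  rec(1, n1, 0)
  mu <- mean(sums)
  mean(abs(sums - mu) >= abs(w_obs - mu) - 1e-9)
}

# brute-force weighted KS running sum from the definition
oracle_gsea_es <- function(scores, set, weight = 1) {
  ord <- order(-scores)
  s <- scores[ord]; ids <- names(s)
  hit <- ids %in% set
  N <- length(s); K <- sum(hit)
  hw <- abs(s)^weight; hw[!hit] <- 0
  hw <- if (sum(hw) > 0) hw / sum(hw) else ifelse(hit, 1 / K, 0)
  rs <- 0; best <- 0
  for (i in seq_len(N)) {
    rs <- rs + if (hit[i]) hw[i] else if (K < N) -1 / (N - K) else 0
    if (abs(rs) > abs(best) || (abs(rs) == abs(best) && rs > best))
      best <- rs
  }
  unname(best)
}
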