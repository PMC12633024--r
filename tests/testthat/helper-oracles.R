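# Independent brute-force oracles.  These re-derive the definitions
# with naive scans and enumerations, deliberately sharing no code with
# the implementations they check.

# --- microhomology: exhaustive overlap scan ---------------------------
oracle_microhomology <- function(deleted, flank5, flank3) {
  L <- nchar(deleted)
  best <- 0
  for (k in seq_len(L - 1)) {
    if (nchar(flank3) >= k &&
        substr(deleted, 1, k) == substr(flank3, 1, k)) best <- max(best, k)
    if (nchar(flank5) >= k &&
        substr(deleted, L - k + 1, L) ==
        substr(flank5, nchar(flank5) - k + 1, nchar(flank5)))
      best <- max(best, k)
  }
  best
}

# --- Fisher exact p: full enumeration over the hypergeometric support -
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(x)
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1), numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- Sig3 posterior: direct unnormalized products (small counts only) -
oracle_posterior <- function(catalog, pos, neg, prior) {
  eps <- 1e-9
  pos <- (pos + eps) / sum(pos + eps)
  neg <- (neg + eps) / sum(neg + eps)
  lp <- prod(pos^catalog)
  ln <- prod(neg^catalog)
  prior * lp / (prior * lp + (1 - prior) * ln)
}

# --- scar scores: naive per-definition re-derivation ------------------
# merges runs by explicit left-to-right scanning, enumerates candidate
# regions, and counts each scar from its printed definition
oracle_scars_sample <- function(seg, genome, loh_min = 15e6, lst_min = 10e6,
                                smooth = 3e6, tol = 1e4) {
  n_loh <- n_tai <- n_lst <- 0
  for (ch in unique(seg$chrom)) {
    L <- genome$chrom_lengths[[ch]]
    s <- seg[seg$chrom == ch, ]
    s <- s[order(s$start), ]
    merge_runs <- function(flag) {
      regions <- list()
      i <- 1
      while (i <= nrow(s)) {
        if (!flag[i]) { i <- i + 1; next }
        j <- i
        while (j < nrow(s) && flag[j + 1] && s$start[j + 1] - s$end[j] <= 1)
          j <- j + 1
        regions[[length(regions) + 1]] <- c(s$start[i], s$end[j])
        i <- j + 1
      }
      regions
    }
    for (r in merge_runs(s$minor < 1)) {
      is_whole <- r[1] <= tol && r[2] >= L - tol
      if (r[2] - r[1] > loh_min && !is_whole) n_loh <- n_loh + 1
    }
    cen <- genome$centromeres[genome$centromeres$chrom == ch, ]
    if (!nrow(cen)) next
    for (r in merge_runs(s$major != s$minor)) {
      reaches_telomere <- r[1] <= tol || r[2] >= L - tol
      crosses <- r[1] < cen$end && r[2] > cen$start
      if (reaches_telomere && !crosses) n_tai <- n_tai + 1
    }
    for (arm in list(c(0, cen$start), c(cen$end, L))) {
      a <- s[s$end > arm[1] & s$start < arm[2], ]
      if (!nrow(a)) next
      a$start <- pmax(a$start, arm[1]); a$end <- pmin(a$end, arm[2])
      merge_fixpoint <- function(a) {
        repeat {
          merged <- FALSE
          if (nrow(a) >= 2) for (i in 1:(nrow(a) - 1)) {
            if (a$start[i + 1] - a$end[i] < smooth &&
                a$major[i] == a$major[i + 1] &&
                a$minor[i] == a$minor[i + 1]) {
              a$end[i] <- a$end[i + 1]
              a <- a[-(i + 1), ]
              merged <- TRUE
              break
            }
          }
          if (!merged) return(a)
        }
      }
      # coalesce equal-CN neighbors, drop sub-smooth segments, coalesce
      # again across the gaps the dropped segments leave
      a <- merge_fixpoint(a)
      a <- a[a$end - a$start >= smooth, ]
      a <- merge_fixpoint(a)
      if (nrow(a) >= 2) for (i in 1:(nrow(a) - 1)) {
        big <- a$end[i] - a$start[i] >= lst_min &&
          a$end[i + 1] - a$start[i + 1] >= lst_min
        close <- a$start[i + 1] - a$end[i] < smooth
        changed <- a$major[i] != a$major[i + 1] || a$minor[i] != a$minor[i + 1]
        if (big && close && changed) n_lst <- n_lst + 1
      }
    }
  }
  c(n_loh_segments = n_loh, n_tai = n_tai, n_lst = n_lst)
}

# --- ssGSEA: literal step-by-step walk --------------------------------
oracle_ssgsea_one <- function(expr_col, gene_names, set, tau) {
  ord <- order(expr_col, decreasing = TRUE)
  genes <- gene_names[ord]
  r <- rank(expr_col)[ord]
  inset <- genes %in% set
  w <- abs(r)^tau
  num <- 0
  p_in <- 0; p_out <- 0
  sum_w_in <- sum(w[inset])
  n_out <- sum(!inset)
  es <- 0
  for (i in seq_along(genes)) {
    if (inset[i]) p_in <- p_in + w[i] / sum_w_in
    else p_out <- p_out + 1 / n_out
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# random segment genome for scar-oracle comparisons
random_segment_genome <- function(sid, genome, p_loh = 0.3, p_amp = 0.25,
                                  mean_breaks = 6) {
  rows <- list()
  for (ch in names(genome$chrom_lengths)) {
    L <- genome$chrom_lengths[[ch]]
    nb <- rpois(1, mean_breaks)
    bounds <- sort(unique(c(0, sample.int(L - 1, nb), L)))
    ns <- length(bounds) - 1
    u <- runif(ns)
    minor <- ifelse(u < p_loh, 0, 1)
    major <- ifelse(u < p_loh, 1,
                    ifelse(u < p_loh + p_amp, sample(2:4, ns, TRUE), 1))
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = sid, chrom = ch, start = bounds[-length(bounds)],
      end = bounds[-1], major = major, minor = minor,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
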