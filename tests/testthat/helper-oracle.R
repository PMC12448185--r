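# Independent per-base oracles. Everything here works on explicit base
# arrays (one value per base and allele) and deliberately avoids the
# interval arithmetic of the package: the two routes must agree.

# tiny genome small enough for per-base arrays
micro_genome <- function() {
  cn_genome("micro", c("chr1", "chr2", "chr3", "chrX", "chrY"),
            c(2000, 1500, 1000, 600, 400),
            sex_chromosomes = c("chrX", "chrY"))
}

# expand a profile to per-base arrays: list(chrom -> list(major=, minor=))
expand_profile <- function(profile) {
  g <- profile$genome
  cols <- if (profile$mode == "allele") c("cn_major", "cn_minor") else "cn_total"
  out <- lapply(g$chroms, function(ch) {
    len <- unname(g$lengths[[ch]])
    arrs <- lapply(cols, function(cc) rep(NA_real_, len))
    names(arrs) <- cols
    seg <- profile$segments[profile$segments$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(seg))) {
      ix <- (seg$start[i] + 1):seg$end[i]
      for (cc in cols) arrs[[cc]][ix] <- seg[[cc]][i]
    }
    arrs
  })
  names(out) <- g$chroms
  out
}

oracle_scope_chroms <- function(genome, scope, sex) {
  auto <- setdiff(genome$chroms, genome$sex_chromosomes)
  sexc <- if (sex == "male") genome$sex_chromosomes
          else genome$sex_chromosomes[1]
  switch(scope, autosomes = auto, sex = sexc, genome = c(auto, sexc))
}

# all six features from per-base arrays
oracle_features <- function(profile, scope) {
  g <- profile$genome
  sex <- profile$sex
  chroms <- oracle_scope_chroms(g, scope, sex)
  arrs <- expand_profile(profile)[chroms]
  total_len <- sum(g$lengths[chroms])
  mono <- bi <- gnd <- hemi <- nulli <- ai <- 0
  steps <- numeric(0)
  bp_major <- bp_minor <- bp_total <- 0
  for (ch in chroms) {
    a <- arrs[[ch]]
    nm <- if (ch %in% g$sex_chromosomes) {
      if (sex == "male") c(1, 0)
      else if (ch == g$sex_chromosomes[1]) c(1, 1) else c(0, 0)
    } else c(1, 1)
    maj <- a$cn_major; min_ <- a$cn_minor
    mono <- mono + sum(!is.na(maj) | !is.na(min_))
    bi <- bi + sum(!is.na(maj) & !is.na(min_))
    gnd <- gnd + sum((!is.na(maj) & maj != nm[1]) |
                     (!is.na(min_) & min_ != nm[2]))
    lost_major <- !is.na(maj) & maj == 0 & nm[1] > 0
    lost_minor <- !is.na(min_) & min_ == 0 & nm[2] > 0
    hemi <- hemi + sum(lost_major | lost_minor)
    nulli <- nulli + sum(lost_major & (nm[2] == 0 | lost_minor))
    ai <- ai + sum(!is.na(maj) & !is.na(min_) & maj != min_)
    n <- length(maj)
    if (n > 1) {
      chg_major <- !is.na(maj[-1]) & !is.na(maj[-n]) & maj[-1] != maj[-n]
      chg_minor <- !is.na(min_[-1]) & !is.na(min_[-n]) & min_[-1] != min_[-n]
      bp_major <- bp_major + sum(chg_major)
      bp_minor <- bp_minor + sum(chg_minor)
      bp_total <- bp_total + sum(chg_major | chg_minor)
      steps <- c(steps, abs(maj[-1] - maj[-n])[chg_major],
                 abs(min_[-1] - min_[-n])[chg_minor])
    }
  }
  list(coverage = c(mono = mono, bi = bi) / total_len,
       gnd = gnd / total_len,
       loh = c(hemi = hemi, nulli = nulli) / total_len,
       ai = ai / total_len,
       breakpoints = c(major = bp_major, minor = bp_minor, total = bp_total),
       breakpoint_step = if (length(steps)) mean(steps) else NA_real_)
}

# per-base imputation: territory (any allele assigned) is filled by
# nearest-neighbor with the floor-midpoint rule; both allele values are
# copied from the flanking base.
oracle_impute <- function(profile, method) {
  g <- profile$genome
  arrs <- expand_profile(profile)
  for (ch in g$chroms) {
    a <- arrs[[ch]]
    covered <- !is.na(a$cn_major) | !is.na(a$cn_minor)
    len <- length(covered)
    fill_pair <- if (method == "diploid") {
      if (ch %in% g$sex_chromosomes) {
        if (profile$sex == "male") c(1, 0)
        else if (ch == g$sex_chromosomes[1]) c(1, 1) else c(0, 0)
      } else c(1, 1)
    } else c(0, 0)
    if (!any(covered)) {
      arrs[[ch]]$cn_major <- rep(fill_pair[1], len)
      arrs[[ch]]$cn_minor <- rep(fill_pair[2], len)
      next
    }
    if (method != "extension") {
      a$cn_major[!covered] <- fill_pair[1]
      a$cn_minor[!covered] <- fill_pair[2]
      arrs[[ch]] <- a
      next
    }
    runs <- rle(covered)
    pos <- cumsum(c(1, runs$lengths))
    for (r in seq_along(runs$lengths)) {
      if (runs$values[r]) next
      s <- pos[r]; e <- pos[r + 1] - 1  # 1-based inclusive gap run
      if (s == 1) {              # leading gap: copy right neighbor
        src <- e + 1
        a$cn_major[s:e] <- a$cn_major[src]; a$cn_minor[s:e] <- a$cn_minor[src]
      } else if (e == len) {     # trailing gap: copy left neighbor
        src <- s - 1
        a$cn_major[s:e] <- a$cn_major[src]; a$cn_minor[s:e] <- a$cn_minor[src]
      } else {                   # interior: left half = floor(gap/2)
        gap <- e - s + 1
        half <- floor(gap / 2)
        if (half > 0) {
          a$cn_major[s:(s + half - 1)] <- a$cn_major[s - 1]
          a$cn_minor[s:(s + half - 1)] <- a$cn_minor[s - 1]
        }
        a$cn_major[(s + half):e] <- a$cn_major[e + 1]
        a$cn_minor[(s + half):e] <- a$cn_minor[e + 1]
      }
    }
    arrs[[ch]] <- a
  }
  arrs
}

# independent re-simulation of the greedy merge loop (recursive phrasing)
oracle_merge_bp <- function(pos, m) {
  pos <- sort(unique(as.numeric(pos)))
  if (!length(pos)) return(numeric(0))
  if (m <= 0) return(pos)
  anchor <- pos[1]
  cluster <- pos[pos - anchor <= m]
  rest <- pos[pos - anchor > m]
  unique(c(floor(mean(cluster)), oracle_merge_bp(rest, m)))
}

# exhaustive knee evaluation straight from the angle definition
oracle_knee <- function(values) {
  tt <- sort(unique(values))
  yy <- sapply(tt, function(t) sum(values <= t))
  n <- length(tt)
  tn <- (tt - tt[1]) / (tt[n] - tt[1])
  yn <- (yy - yy[1]) / (yy[n] - yy[1])
  best <- NA; best_angle <- -Inf; sign <- NA
  for (i in 2:(n - 1)) {
    v1 <- c(tn[i], yn[i]); v2 <- c(1 - tn[i], 1 - yn[i])
    ang <- atan2(v1[1] * v2[2] - v1[2] * v2[1], sum(v1 * v2))
    if (abs(ang) > best_angle) { best_angle <- abs(ang); best <- i; sign <- ang }
  }
  list(index = best, value = tt[best],
       kind = if (sign < 0) "knee" else "elbow", angle = sign)
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mwu_exact <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  u_of <- function(ix) {
    r <- rank(pool)
    sum(r[ix]) - na * (na + 1) / 2
  }
  obs <- u_of(seq_len(na))
  mu <- na * length(b) / 2
  combs <- utils::combn(length(pool), na)
  us <- apply(combs, 2, function(ix) {
    r <- rank(pool)
    sum(r[ix]) - na * (na + 1) / 2
  })
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# random gapped allele-specific profile on a small genome
rand_profile <- function(genome, id = "r1", seg_size = 200,
                         p_gap = 0.3, p_na_minor = 0.1, sex = NULL) {
  segs <- list()
  for (ch in genome$chroms) {
    len <- unname(genome$lengths[[ch]])
    bounds <- unique(c(0, sort(sample(1:(len - 1),
                                      max(1, round(len / seg_size)))), len))
    for (i in seq_len(length(bounds) - 1)) {
      if (runif(1) < p_gap) next
      maj <- sample(0:4, 1)
      min_ <- if (runif(1) < p_na_minor) NA_real_ else sample(0:min(maj, 2), 1)
      segs[[length(segs) + 1]] <- data.frame(
        chrom = ch, start = bounds[i], end = bounds[i + 1],
        cn_major = maj, cn_minor = min_)
    }
  }
  if (!length(segs))
    segs <- list(data.frame(chrom = genome$chroms[1], start = 0,
                            end = 100, cn_major = 2, cn_minor = 1))
  cn_profile(id, do.call(rbind, segs), genome, sex = sex)
}

# expand imputed interval profile and compare with per-base oracle arrays
expect_matches_oracle_impute <- function(profile, method) {
  imp <- impute(profile, method)
  got <- expand_profile(imp)
  want <- oracle_impute(profile, method)
  for (ch in profile$genome$chroms) {
    expect_equal(got[[ch]]$cn_major, want[[ch]]$cn_major,
                 info = paste(method, ch, "major"))
    expect_equal(got[[ch]]$cn_minor, want[[ch]]$cn_minor,
                 info = paste(method, ch, "minor"))
  }
  invisible(imp)
}
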