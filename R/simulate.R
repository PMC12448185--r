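# Seeded synthetic cohorts with ground truth. The generator emulates the
# gross structure of real pan-cancer SCNA data — class-specific arm-level
# gains/losses and focal amplifications on a diploid baseline, a fraction
# of whole-genome-doubled samples, per-segment jitter, and missing-data
# gaps concentrated around centromere-like coordinates — so every module
# is testable without downloads. It does not emulate caller noise models,
# subclonality or correlated event co-occurrence.

#' Describe one planted copy-number event
#'
#' @param type `"gain"` (add `delta` to the major allele), `"loss"`
#'   (subtract from the minor allele, floored at 0), `"focal_amp"` (set
#'   the major allele to `cn`), or `"loh"` (minor allele to 0; major
#'   allele takes the lost copy, keeping the total).
#' @param chrom,start,end Event footprint (0-based half-open).
#' @param delta Copy-number change for gain/loss (default 1).
#' @param cn Target major CN for focal amplifications (default 8).
#' @param prob Probability that a sample of the class carries the event.
#' @return A `sim_event` list.
#' @export
sim_event <- function(type = c("gain", "loss", "focal_amp", "loh"),
                      chrom, start, end, delta = 1, cn = 8, prob = 1) {
  type <- match.arg(type)
  stopifnot(start >= 0, end > start, prob >= 0, prob <= 1)
  structure(list(type = type, chrom = chrom, start = start, end = end,
                 delta = delta, cn = cn, prob = prob), class = "sim_event")
}

#' Describe a sample class as a set of event templates
#' @param name Class label.
#' @param events List of [sim_event()] objects.
#' @return A `sim_class` list.
#' @export
sim_class <- function(name, events = list()) {
  structure(list(name = name, events = events), class = "sim_class")
}

default_sim_classes <- function(genome) {
  # two classes echoing the shape of real class mean profiles: one with an
  # arm-level gain, one dominated by a focal amplification plus a LoH tract
  c1len <- chrom_length(genome, genome$chroms[1])
  c2len <- chrom_length(genome, genome$chroms[2])
  list(
    sim_class("arm_gain", list(
      sim_event("gain", genome$chroms[1], floor(c1len / 2), c1len, delta = 1),
      sim_event("loss", genome$chroms[2], 0, floor(c2len / 4), prob = 0.5))),
    sim_class("focal_amp", list(
      sim_event("focal_amp", genome$chroms[2], floor(c2len * 0.4),
                floor(c2len * 0.5), cn = 8),
      sim_event("loh", genome$chroms[1], 0, floor(c1len / 4), prob = 0.7))))
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a small but realistic cohort: 25 samples per class,
#' ~5% of each genome missing (matching the pre-filter CN-coverage range
#' of public pan-cancer cohorts), a quarter of samples whole-genome
#' doubled, and no jitter.
#'
#' @param genome A [cn_genome] (default [toy_genome()]).
#' @param n_samples Samples per class.
#' @param classes List of [sim_class()] templates; default: one arm-gain
#'   class and one focal-amplification class.
#' @param gap_fraction Fraction of each sample's genome left missing.
#' @param gap_placement `"centromere"` concentrates gaps around the
#'   chromosome midpoints (mimicking real missingness around centromeres),
#'   `"uniform"` scatters them.
#' @param wgd_probability Probability that a sample's CNs are all doubled.
#' @param noise Standard deviation of per-segment CN jitter (applied per
#'   segment, keeping profiles piecewise constant; values floored at 0).
#' @param seed Integer seed; the same config and seed give an identical
#'   cohort.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome = toy_genome(), n_samples = 25,
                       classes = default_sim_classes(genome),
                       gap_fraction = 0.05,
                       gap_placement = c("centromere", "uniform"),
                       wgd_probability = 0.25, noise = 0, seed = 1L) {
  gap_placement <- match.arg(gap_placement)
  stopifnot(gap_fraction >= 0, gap_fraction < 1,
            wgd_probability >= 0, wgd_probability <= 1, noise >= 0)
  for (cl in classes) for (ev in cl$events) {
    if (!ev$chrom %in% genome$chroms || ev$end > chrom_length(genome, ev$chrom))
      stop("event outside genome: ", ev$chrom, ":", ev$start, "-", ev$end,
           call. = FALSE)
  }
  structure(list(genome = genome, n_samples = n_samples, classes = classes,
                 gap_fraction = gap_fraction, gap_placement = gap_placement,
                 wgd_probability = wgd_probability, noise = noise,
                 seed = as.integer(seed)), class = "sim_config")
}

# piecewise-constant editing of a (major, minor) segment table
apply_event <- function(seg, ev) {
  pieces <- list()
  for (i in seq_len(nrow(seg))) {
    row <- seg[i]
    if (row$chrom != ev$chrom || row$start >= ev$end || row$end <= ev$start) {
      pieces[[length(pieces) + 1L]] <- row
      next
    }
    cuts <- sort(unique(c(row$start, row$end,
                          max(row$start, ev$start), min(row$end, ev$end))))
    for (j in seq_len(length(cuts) - 1L)) {
      piece <- data.table::copy(row)
      piece[, c("start", "end") := .(cuts[j], cuts[j + 1])]
      if (cuts[j] >= ev$start && cuts[j + 1] <= ev$end) {
        piece[, c("cn_major", "cn_minor") := {
          switch(ev$type,
            gain = .(cn_major + ev$delta, cn_minor),
            loss = .(cn_major, pmax(cn_minor - ev$delta, 0)),
            focal_amp = .(ev$cn, cn_minor),
            loh = .(cn_major + cn_minor, 0))
        }]
      }
      pieces[[length(pieces) + 1L]] <- piece
    }
  }
  data.table::rbindlist(pieces)
}

punch_gaps <- function(seg, genome, gap_fraction, placement, rng_round) {
  if (gap_fraction <= 0) return(seg)
  out <- list()
  for (ch in genome$chroms) {
    len <- chrom_length(genome, ch)
    chseg <- seg[seg$chrom == ch]
    if (nrow(chseg) == 0L) next
    gap_len <- floor(len * gap_fraction)
    if (gap_len < 1) { out[[ch]] <- chseg; next }
    center <- if (placement == "centromere") {
      floor(len / 2) + rng_round(-len / 20, len / 20)
    } else {
      rng_round(gap_len / 2, len - gap_len / 2)
    }
    g0 <- max(0, min(center - floor(gap_len / 2), len - gap_len))
    g1 <- g0 + gap_len
    kept <- list()
    for (i in seq_len(nrow(chseg))) {
      row <- chseg[i]
      if (row$end <= g0 || row$start >= g1) { kept[[length(kept) + 1L]] <- row; next }
      if (row$start < g0) {
        left <- data.table::copy(row); left[, end := g0]
        kept[[length(kept) + 1L]] <- left
      }
      if (row$end > g1) {
        right <- data.table::copy(row); right[, start := g1]
        kept[[length(kept) + 1L]] <- right
      }
    }
    out[[ch]] <- data.table::rbindlist(kept)
  }
  data.table::rbindlist(out)
}

#' Generate a synthetic cohort with ground truth
#'
#' Each sample starts from a fully diploid (1, 1) baseline, receives its
#' class's events (each with its own carrier probability), is optionally
#' whole-genome doubled, jittered per segment, and finally punched with
#' one missing gap per chromosome sized to `gap_fraction`.
#'
#' @param config A [sim_config()].
#' @return List with `cohort` (a [cn_cohort]) and `truth` (a data.table
#'   with one row per sample: class, sex, WGD status, planted events) plus
#'   `complete` (the pre-gap cohort, i.e. the true per-base CN).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- config$genome
  set.seed(config$seed)
  rng_round <- function(lo, hi) floor(stats::runif(1, lo, hi))
  profiles <- list()
  complete <- list()
  truth <- list()
  for (ci in seq_along(config$classes)) {
    cl <- config$classes[[ci]]
    for (k in seq_len(config$n_samples)) {
      id <- sprintf("%s_%02d", cl$name, k)
      sex <- if (stats::runif(1) < 0.5) "male" else "female"
      seg <- data.table::data.table(
        chrom = genome$chroms, start = 0, end = unname(genome$lengths),
        cn_major = 1, cn_minor = 1)
      if (!is.null(genome$sex_chromosomes)) {
        xy <- genome$sex_chromosomes
        if (sex == "male") {
          seg[chrom %in% xy, c("cn_major", "cn_minor") := .(1, 0)]
        } else {
          seg <- seg[chrom != xy[2]]  # female genome carries no Y
        }
      }
      carried <- character(0)
      for (ev in cl$events) {
        if (stats::runif(1) <= ev$prob) {
          seg <- apply_event(seg, ev)
          carried <- c(carried, sprintf("%s:%s:%g-%g", ev$type, ev$chrom,
                                        ev$start, ev$end))
        }
      }
      wgd <- stats::runif(1) < config$wgd_probability
      if (wgd) seg[, c("cn_major", "cn_minor") := .(cn_major * 2, cn_minor * 2)]
      if (config$noise > 0) {
        jit <- stats::rnorm(nrow(seg), 0, config$noise)
        seg[, cn_major := pmax(cn_major + jit, 0)]
        seg[, cn_minor := pmax(cn_minor + jit, 0)]
      }
      full <- cn_profile(id, seg, genome, sex = sex)
      full <- merge_equal_neighbors(full)
      gapped <- punch_gaps(full$segments, genome, config$gap_fraction,
                           config$gap_placement, rng_round)
      gapped <- gapped[chrom %in% unique(full$segments$chrom)]
      complete[[id]] <- full
      profiles[[id]] <- cn_profile(id, gapped, genome, sex = sex)
      truth[[id]] <- data.table::data.table(
        sample_id = id, class = cl$name, sex = sex, wgd = wgd,
        events = paste(carried, collapse = ";"))
    }
  }
  list(cohort = cn_cohort(profiles),
       complete = cn_cohort(complete),
       truth = data.table::rbindlist(truth))
}
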