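# Reference-genome model: ordered chromosomes with lengths, designated sex
# chromosomes, and the sex-aware expected ("normal") copy number of every
# chromosome/allele pair. All coordinates in the package are 0-based
# half-open (BED-compatible).

#' Construct a reference genome
#'
#' A reference genome is an ordered set of chromosomes with lengths plus a
#' designation of which two chromosomes act as the X-like and Y-like sex
#' chromosomes. It underpins coordinate validation, sex-aware feature
#' denominators and expected normal copy numbers.
#'
#' @param name Genome identifier, e.g. `"hg19"` or `"toy"`.
#' @param chroms Character vector of chromosome names (unique, ordered).
#' @param lengths Integer-like vector of chromosome lengths in bases (> 0).
#' @param sex_chromosomes Character vector of length 2: the X-like and
#'   Y-like chromosome names. Use `NULL` for a genome without sex
#'   chromosomes (all chromosomes are then treated as autosomes).
#'
#' @return An object of class `cn_genome`.
#' @examples
#' g <- cn_genome("toy", c("c1", "cX", "cY"), c(1e5, 5e4, 2e4),
#'                sex_chromosomes = c("cX", "cY"))
#' chrom_lengths(g)
#' @export
cn_genome <- function(name, chroms, lengths, sex_chromosomes = c("chrX", "chrY")) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) != length(lengths))
    stop("`chroms` and `lengths` must have equal length", call. = FALSE)
  if (anyDuplicated(chroms))
    stop("chromosome names must be unique", call. = FALSE)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive", call. = FALSE)
  if (!is.null(sex_chromosomes)) {
    sex_chromosomes <- as.character(sex_chromosomes)
    if (length(sex_chromosomes) != 2L)
      stop("`sex_chromosomes` must name exactly two chromosomes (X-like, Y-like)",
           call. = FALSE)
    if (!all(sex_chromosomes %in% chroms))
      stop("sex chromosomes must be members of `chroms`", call. = FALSE)
  }
  structure(
    list(name = as.character(name)[1],
         chroms = chroms,
         lengths = stats::setNames(lengths, chroms),
         sex_chromosomes = sex_chromosomes),
    class = "cn_genome")
}

#' @export
print.cn_genome <- function(x, ...) {
  cat(sprintf("<cn_genome> %s: %d chromosomes, %.1f Mb total\n",
              x$name, length(x$chroms), sum(x$lengths) / 1e6))
  if (!is.null(x$sex_chromosomes))
    cat(sprintf("  sex chromosomes: %s (X-like), %s (Y-like)\n",
                x$sex_chromosomes[1], x$sex_chromosomes[2]))
  invisible(x)
}

#' Load a reference genome by name or from a chrom.sizes file
#'
#' `"hg19"` and `"hg38"` tables (UCSC primary chromosomes) are bundled with
#' the package; any other value is taken as a path to a two-column TSV in
#' UCSC chrom.sizes format (name, length).
#'
#' @param name `"hg19"`, `"hg38"`, or a file path.
#' @param sex_chromosomes Names of the X-like and Y-like chromosomes, or
#'   `NULL` if absent from the table.
#' @return A [cn_genome] object.
#' @export
load_genome <- function(name, sex_chromosomes = c("chrX", "chrY")) {
  path <- if (name %in% c("hg19", "hg38")) {
    system.file("extdata", paste0(name, ".chrom.sizes"), package = "cnseg",
                mustWork = TRUE)
  } else name
  if (!file.exists(path))
    stop("no bundled genome or chrom.sizes file: ", name, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  if (!is.null(sex_chromosomes) && !all(sex_chromosomes %in% tab$chrom))
    sex_chromosomes <- NULL
  cn_genome(if (file.exists(name)) tools::file_path_sans_ext(basename(name)) else name,
            tab$chrom, tab$length, sex_chromosomes)
}

#' Tiny fictional genome for examples and tests
#'
#' Three autosomes plus X and Y, each at most 1 Mb, so that per-base
#' brute-force checks stay cheap and no download is ever needed.
#'
#' @param autosome_lengths Lengths of the autosomes (default 100, 80, 60 kb).
#' @param x_length,y_length Lengths of the sex chromosomes.
#' @return A [cn_genome] object named `"toy"`.
#' @export
toy_genome <- function(autosome_lengths = c(100e3, 80e3, 60e3),
                       x_length = 50e3, y_length = 20e3) {
  n <- length(autosome_lengths)
  cn_genome("toy",
            c(paste0("chr", seq_len(n)), "chrX", "chrY"),
            c(autosome_lengths, x_length, y_length),
            sex_chromosomes = c("chrX", "chrY"))
}

#' Chromosome lengths of a genome
#' @param genome A [cn_genome].
#' @return Named numeric vector of lengths in bases.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "cn_genome"))
  genome$lengths
}

chrom_length <- function(genome, chrom) {
  if (!chrom %in% genome$chroms)
    stop("unknown chromosome '", chrom, "' for genome ", genome$name,
         call. = FALSE)
  unname(genome$lengths[[chrom]])
}

is_autosome <- function(genome, chrom) {
  !(chrom %in% genome$sex_chromosomes)
}

# Chromosomes making up a feature scope for a given sex. The linear genome
# is sex dependent: a female genome carries no Y-like chromosome, so it is
# excluded from both numerators and denominators of her features.
scope_chroms <- function(genome, scope = c("genome", "autosomes", "sex"),
                         sex = c("female", "male")) {
  scope <- match.arg(scope)
  sex <- match.arg(sex)
  auto <- setdiff(genome$chroms, genome$sex_chromosomes)
  sexc <- if (is.null(genome$sex_chromosomes)) character(0)
          else if (sex == "male") genome$sex_chromosomes
          else genome$sex_chromosomes[1]
  switch(scope,
         autosomes = auto,
         sex = sexc,
         genome = c(auto, sexc))
}

#' Expected normal copy number of a chromosome for a given sex
#'
#' The copy number a normal diploid cell of the given sex carries:
#' autosomes are (major, minor) = (1, 1); a male carries (1, 0) on each sex
#' chromosome; a female carries (1, 1) on the X-like chromosome and (0, 0)
#' on the Y-like one. Totals are the allele sums.
#'
#' @param chrom Chromosome name.
#' @param allele One of `"major"`, `"minor"`, `"total"`.
#' @param sex `"female"` or `"male"`.
#' @param genome A [cn_genome].
#' @return A non-negative integer.
#' @examples
#' g <- toy_genome()
#' normal_copy("chr1", "total", "female", g)  # 2
#' normal_copy("chrY", "minor", "male", g)    # 0
#' @export
normal_copy <- function(chrom, allele = c("total", "major", "minor"),
                        sex = c("female", "male"), genome) {
  allele <- match.arg(allele)
  sex <- match.arg(sex)
  if (!chrom %in% genome$chroms)
    stop("unknown chromosome '", chrom, "' for genome ", genome$name,
         call. = FALSE)
  pair <- normal_pair(chrom, sex, genome)
  switch(allele, major = pair[1], minor = pair[2], total = sum(pair))
}

# (major, minor) expectation as an integer pair; vector-safe over chrom
normal_pair <- function(chrom, sex, genome) {
  if (is_autosome(genome, chrom)) return(c(1L, 1L))
  if (sex == "male") return(c(1L, 0L))
  if (chrom == genome$sex_chromosomes[1]) c(1L, 1L) else c(0L, 0L)
}

#' Infer the sex of a sample from its copy-number profile
#'
#' A sample is called male when its profile carries at least one segment on
#' the Y-like chromosome with a non-missing copy number greater than zero
#' (some callers emit explicit CN = 0 rows on Y for female samples), female
#' otherwise. A sex recorded on the profile by the user always wins.
#'
#' @param profile A [cn_profile].
#' @param genome A [cn_genome]; defaults to the profile's genome.
#' @return `"male"` or `"female"`.
#' @export
infer_sex <- function(profile, genome = profile$genome) {
  stopifnot(inherits(profile, "cn_profile"))
  if (!is.null(profile$declared_sex)) return(profile$declared_sex)
  if (is.null(genome$sex_chromosomes)) return("female")
  ychr <- genome$sex_chromosomes[2]
  seg <- profile$segments[profile$segments$chrom == ychr, , drop = FALSE]
  if (nrow(seg) == 0L) return("female")
  cn <- if (profile$mode == "total") seg$cn_total
        else pmax(seg$cn_major, seg$cn_minor, na.rm = TRUE)
  cn[is.na(cn)] <- 0
  if (any(cn > 0)) "male" else "female"
}
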