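#' Write genotype data as VCF 4.2
#'
#' Writers for the package's VCF dialect: a single contig, 1-based `POS`
#' (internal coordinates are 0-based half-open), biallelic A/T records and
#' phased `GT` (`a|b`). Imputation results additionally carry the allele
#' dosage in a `DS` FORMAT field.
#'
#' @param x A [haplotype_panel] or `ls_imputation`.
#' @param path Output file path.
#' @param ... Unused.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, ...) UseMethod("write_vcf")

.vcf_header <- function(contig, length, extra_format = NULL) {
  c("##fileformat=VCFv4.2",
    "##source=impsim",
    sprintf("##contig=<ID=%s,length=%d>", contig, as.integer(length)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    extra_format)
}

#' @rdname write_vcf
#' @export
write_vcf.haplotype_panel <- function(x, path, ...) {
  n <- nrow(x$haplotypes) / 2L
  odd <- seq(1L, 2L * n, by = 2L)
  samp <- sprintf("ind%d", seq_len(n))
  gt <- matrix(paste0(t(x$haplotypes[odd, , drop = FALSE]), "|",
                      t(x$haplotypes[odd + 1L, , drop = FALSE])),
               nrow = ncol(x$haplotypes))
  body <- paste0("1\t", x$positions + 1L, "\t.\tA\tT\t.\tPASS\t.\tGT\t",
                 apply(gt, 1L, paste, collapse = "\t"))
  hdr <- .vcf_header("1", x$sequence_length)
  writeLines(c(hdr,
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samp), collapse = "\t"),
               body), path)
  invisible(path)
}

#' @rdname write_vcf
#' @param sequence_length Contig length for the header (defaults to just
#'   past the last site).
#' @export
write_vcf.ls_imputation <- function(x, path,
                                    sequence_length = max(x$positions) + 1L,
                                    ...) {
  n <- nrow(x$dosage)
  samp <- sprintf("ind%d", seq_len(n))
  gtcode <- c("0|0", "0|1", "1|1")
  cells <- matrix(paste0(gtcode[t(x$genotype) + 1L], ":",
                         format(t(x$dosage), trim = TRUE, digits = 6)),
                  nrow = ncol(x$dosage))
  body <- paste0("1\t", x$positions + 1L, "\t.\tA\tT\t.\tPASS\t.\tGT:DS\t",
                 apply(cells, 1L, paste, collapse = "\t"))
  hdr <- .vcf_header("1", sequence_length,
                     "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Imputed allele dosage\">")
  writeLines(c(hdr,
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samp), collapse = "\t"),
               body), path)
  invisible(path)
}

#' Read a VCF into a haplotype panel or imputed genotypes
#'
#' Reads a biallelic VCF 4.2 with phased `GT`. Records with multiallelic
#' `ALT` are rejected (the pipeline is biallelic by construction), as is a
#' missing `GT`. When a `DS` dosage FORMAT is present the result is an
#' `imputed_genotypes` object (dosage taken from `DS`, best-guess genotype
#' from `GT`; a discrepancy between the two is reported with a warning);
#' otherwise a [haplotype_panel] is returned.
#'
#' @param path VCF file path.
#' @param population Optional population labels: a character vector (one
#'   per sample, recycled) or the path of a two-column TSV
#'   (sample, population) as written by [write_population_tsv()].
#' @param allow_unphased Accept `/`-separated genotypes by assuming they
#'   are phased in written order (simulation truth); default FALSE, in
#'   which case unphased records are an error.
#' @param sequence_length Override for the contig length when the header
#'   carries none.
#' @return A [haplotype_panel], or an `imputed_genotypes` list with
#'   `dosage` and `genotype` matrices (individuals x sites) and 0-based
#'   `positions`.
#' @export
read_vcf <- function(path, population = NULL, allow_unphased = FALSE,
                     sequence_length = NULL) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF: ", conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("multiallelic record at POS ",
         paste(fix[grepl(",", alt, fixed = TRUE), "POS"], collapse = ", "),
         ": only biallelic records are supported")
  fmt <- v@gt[, 1L]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) stop("VCF records lack a GT field")
  gt <- vcfR::extract.gt(v, "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L)
  pos <- as.integer(fix[, "POS"]) - 1L
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  unph <- grepl("/", gt, fixed = TRUE)
  if (any(unph) && !allow_unphased)
    stop("unphased genotypes found; pass allow_unphased = TRUE to treat ",
         "written order as phase (simulation truth)")
  gt2 <- gsub("/", "|", gt, fixed = TRUE)
  al <- strsplit(gt2, "|", fixed = TRUE)
  a1 <- suppressWarnings(as.integer(vapply(al, `[`, character(1), 1L)))
  a2 <- suppressWarnings(as.integer(vapply(al, `[`, character(1), 2L)))
  if (anyNA(a1) || anyNA(a2)) stop("malformed VCF: unparseable GT entries")
  S <- nrow(gt); n <- ncol(gt)
  geno <- t(matrix(a1 + a2, S, n))        # individuals x sites

  if (has_ds) {
    ds <- t(vcfR::extract.gt(v, "DS", as.numeric = TRUE))
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = n)
    bad <- abs(ds - geno) > 0.5 + 1e-9
    if (any(bad))
      warning(sum(bad), " dosage entries disagree with GT rounding; ",
              "DS used for dosage, GT for best-guess genotypes")
    return(structure(list(dosage = ds, genotype = geno, positions = pos,
                          samples = colnames(gt)),
                     class = "imputed_genotypes"))
  }

  h <- matrix(0L, 2L * n, S)
  h[seq(1L, 2L * n, 2L), ] <- t(matrix(a1, S, n))
  h[seq(2L, 2L * n, 2L), ] <- t(matrix(a2, S, n))
  if (is.null(sequence_length)) {
    ctg <- grep("^##contig", v@meta, value = TRUE)
    len <- if (length(ctg)) suppressWarnings(as.numeric(
      sub(".*length=([0-9]+).*", "\\1", ctg[1L]))) else NA_real_
    sequence_length <- if (is.finite(len)) len else max(pos) + 1
  }
  popl <- rep("S", 2L * n)
  if (!is.null(population)) {
    if (length(population) == 1L && file.exists(population)) {
      tab <- utils::read.table(population, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      population <- tab[[2L]][match(colnames(gt), tab[[1L]])]
    }
    popl <- rep(rep_len(population, n), each = 2L)
  }
  haplotype_panel(h, positions = pos, population = popl,
                  sequence_length = sequence_length)
}

#' Write the population sidecar TSV of a panel
#'
#' @param panel A [haplotype_panel].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_tsv <- function(panel, path) {
  n <- nrow(panel$haplotypes) / 2L
  utils::write.table(
    data.frame(sample = sprintf("ind%d", seq_len(n)),
               population = panel$population[seq(1L, 2L * n, by = 2L)]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a marker selection as BED / TSV
#'
#' BED rows are 0-based half-open single-bp intervals of the observed
#' (scaffold) markers; the TSV lists every universe site with an
#' `observed` flag.
#'
#' @param selection A `marker_selection`.
#' @param positions bp positions (0-based) of the panel sites the
#'   selection indexes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_bed <- function(selection, positions, path) {
  p <- positions[selection$observed]
  writeLines(sprintf("1\t%d\t%d\tsite%d", p, p + 1L, selection$observed),
             path)
  invisible(path)
}

#' @rdname write_selection_bed
#' @export
write_selection_tsv <- function(selection, path) {
  utils::write.table(
    data.frame(site = selection$sites,
               observed = as.integer(selection$sites %in% selection$observed),
               scheme = selection$scheme),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_selection_bed
#' @export
read_selection_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  .new_selection(tab$scheme[1L], tab$site, tab$site[tab$observed == 1L])
}

#' Packaged benchmark tables
#'
#' Published benchmark values from a factorial genotype-imputation
#' simulation study on pig sequence data (Beagle5.1 vs Minimac4; four
#' populations; 20,000 diploids over a 10 Mb chromosome at full scale).
#' They drive the package's aggregation layer in tests and examples:
#' `"T4"` (alias `"marker_counts"`) -- segregating-variant counts per
#' population and density level; `"T5"` (`"reliability"`) -- mean
#' imputation reliability per method, reference size and density for
#' sequencing-derived (LCWGS) panels; `"T6"` (`"error_rate"`) -- the
#' corresponding allelic error rates in percent.
#'
#' @param table_id One of `"T4"`, `"T5"`, `"T6"` or the aliases above.
#' @return `load_fixture()`: the table as packaged. `fixture_cells()`: a
#'   long cell table (one row per design cell, column `value`) suitable
#'   for [marginal_mean()] and [factor_cvs()].
#' @export
load_fixture <- function(table_id) {
  key <- switch(as.character(table_id),
                T4 = , marker_counts = "benchmark_marker_counts.csv",
                T5 = , reliability = "benchmark_reliability.csv",
                T6 = , error_rate = "benchmark_error_rate.csv",
                stop("unknown fixture table id: ", table_id))
  f <- system.file("extdata", key, package = "impsim", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE, comment.char = "#")
}

#' @rdname load_fixture
#' @export
fixture_cells <- function(table_id) {
  tab <- load_fixture(table_id)
  if ("count" %in% names(tab)) return(tab)   # T4 is already long
  tab
}
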