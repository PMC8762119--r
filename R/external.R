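#' Run an external imputation tool through the VCF interface
#'
#' Adapter that makes shell-invoked imputers (e.g. Beagle5.1 or Minimac4)
#' pluggable into the pipeline's method slot: it writes the target scaffold
#' and the reference panel as VCF 4.2, substitutes the file paths into a
#' command template, invokes the tool, and parses the imputed VCF back
#' into the hidden-site result layout used by [impute_genotypes()].
#'
#' @param scaffold A [haplotype_panel] of the target individuals at the
#'   observed sites.
#' @param reference A [haplotype_panel] of the reference individuals over
#'   all sites.
#' @param selection A `marker_selection` over the reference site list.
#' @param command Command template with placeholders `{scaffold}`,
#'   `{reference}` and `{out}` (the output VCF path the tool must write).
#' @param dir Working directory for the exchanged files (a temporary
#'   directory by default).
#' @return An object of class `c("external_imputation", "ls_imputation")`
#'   with `dosage`, `genotype`, `positions` over the hidden sites.
#' @export
external_impute <- function(scaffold, reference, selection, command,
                            dir = tempfile("imputation")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  exe <- strsplit(trimws(command), "[[:space:]]+")[[1L]][1L]
  if (Sys.which(exe) == "" && !file.exists(exe))
    stop("imputation tool not found: '", exe, "'")
  sc_path <- file.path(dir, "scaffold.vcf")
  ref_path <- file.path(dir, "reference.vcf")
  out_path <- file.path(dir, "imputed.vcf")
  write_vcf(scaffold, sc_path)
  write_vcf(reference, ref_path)
  cmd <- command
  cmd <- gsub("{scaffold}", sc_path, cmd, fixed = TRUE)
  cmd <- gsub("{reference}", ref_path, cmd, fixed = TRUE)
  cmd <- gsub("{out}", out_path, cmd, fixed = TRUE)
  status <- system(cmd)
  if (status != 0L || !file.exists(out_path))
    stop("external imputer failed (exit status ", status, ")")
  res <- read_vcf(out_path, allow_unphased = TRUE)
  if (inherits(res, "haplotype_panel")) {
    geno <- panel_genotypes(res)
    dos <- geno
    pos <- res$positions
  } else {
    geno <- res$genotype
    dos <- res$dosage
    pos <- res$positions
  }
  hidden_pos <- reference$positions[selection$hidden]
  idx <- match(hidden_pos, pos)
  if (anyNA(idx))
    stop("site-set mismatch: imputed VCF is missing ", sum(is.na(idx)),
         " hidden site(s), e.g. POS ",
         hidden_pos[which(is.na(idx))[1L]] + 1L)
  structure(
    list(dosage = dos[, idx, drop = FALSE],
         genotype = geno[, idx, drop = FALSE],
         confidence = rep(NA_real_, length(idx)),
         hidden = selection$hidden,
         positions = hidden_pos,
         n_reference = nrow(reference$haplotypes) / 2L,
         command = command),
    class = c("external_imputation", "ls_imputation"))
}

#' Build a scenario engine from an external command template
#'
#' Returns a function with the engine signature accepted by
#' [run_scenario()], closing over the command template.
#'
#' @inheritParams external_impute
#' @return A function `(scaffold, reference, selection, params)`.
#' @export
external_engine <- function(command) {
  force(command)
  function(scaffold, reference, selection, params)
    external_impute(scaffold, reference, selection, command)
}
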