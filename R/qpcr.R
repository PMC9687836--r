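#' Fit a qPCR standard curve
#'
#' Least-squares line `Ct = slope * log10(copies) + intercept` through a
#' serial-dilution series. A valid assay has a negative slope (about -3.32
#' cycles per ten-fold dilution at perfect efficiency).
#'
#' @param copies known template amounts (gene copies), > 0.
#' @param ct observed threshold cycles.
#' @param assay target name recorded on the curve.
#' @return an object of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared` and the dilution points.
#' @export
fit_standard_curve <- function(copies, ct, assay = "assay") {
  if (length(copies) != length(ct))
    stop("copies and ct must have equal length", call. = FALSE)
  if (length(copies) < 3)
    stop("a standard curve needs at least 3 dilution points", call. = FALSE)
  if (any(copies <= 0)) stop("copies must be > 0", call. = FALSE)
  lg <- log10(copies)
  if (diff(range(lg)) < 2)
    stop("dilution points must span at least 2 log10 units", call. = FALSE)
  fit <- lm(ct ~ lg)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope)) stop("degenerate dilution series", call. = FALSE)
  if (slope >= 0)
    warning("standard curve has non-negative slope; assay likely failed",
            call. = FALSE)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ct - mean(ct))^2)
  structure(list(assay = assay, slope = slope,
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 dilution_points = data.frame(copies = copies, ct = ct)),
            class = "standard_curve")
}

#' Absolute quantification from Ct
#'
#' `C = 10^((Ct - intercept) / slope)` in gene copies per uL. Missing Ct (no
#' amplification) maps to concentration 0; which entries were absent is
#' recorded in the `no_amplification` attribute.
#'
#' @param ct threshold cycles (NA = no amplification).
#' @param curve a [fit_standard_curve()] result (or any list with `slope` and
#'   `intercept`).
#' @return numeric vector of concentrations in gene copies per uL.
#' @export
quantify_target <- function(ct, curve) {
  if (is.null(curve$slope) || curve$slope == 0)
    stop("curve slope must be nonzero", call. = FALSE)
  conc <- ifelse(is.na(ct), 0, 10^((ct - curve$intercept) / curve$slope))
  attr(conc, "no_amplification") <- is.na(ct)
  conc
}

#' Quantify a qPCR plate against per-assay standard curves
#'
#' Replicate wells of the same (sample, assay) are averaged on the Ct scale
#' before quantification (a well with no amplification counts as absent only
#' if all replicates failed; otherwise failed replicates are dropped from the
#' mean).
#'
#' @param plate data.frame with columns `sample_id`, `assay`, `ct`.
#' @param curves named list of `standard_curve` objects, one per assay.
#' @return numeric matrix, assays (rows) x samples (columns), gene copies
#'   per uL.
#' @export
quantify_plate <- function(plate, curves) {
  assays <- unique(plate$assay)
  missing_curves <- setdiff(assays, names(curves))
  if (length(missing_curves) > 0)
    stop("no standard curve for assay: ",
         paste(missing_curves, collapse = ", "), call. = FALSE)
  samples <- unique(plate$sample_id)
  out <- matrix(0, nrow = length(assays), ncol = length(samples),
                dimnames = list(assays, samples))
  for (a in assays) {
    sub <- plate[plate$assay == a, , drop = FALSE]
    mean_ct <- tapply(sub$ct, sub$sample_id, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else mean(v)
    })
    out[a, names(mean_ct)] <- quantify_target(as.numeric(mean_ct), curves[[a]])
  }
  out
}

#' 16S copy-number correction
#'
#' Divides per-taxon gene-copy concentrations by the taxon's 16S rRNA gene
#' copies per genome, yielding organism-equivalent concentrations.
#'
#' @param gene_copies numeric matrix (taxa x samples) or named vector of
#'   gene-copy concentrations.
#' @param copy_numbers named numeric vector, taxon -> copies per genome
#'   (>= 1).
#' @return object of the same shape in organism equivalents.
#' @export
copy_number_correct <- function(gene_copies, copy_numbers) {
  taxa <- if (is.matrix(gene_copies)) rownames(gene_copies)
          else names(gene_copies)
  missing <- setdiff(taxa, names(copy_numbers))
  if (length(missing) > 0)
    stop("no 16S copy number for taxon: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(copy_numbers[taxa] < 1))
    stop("copy numbers must be >= 1", call. = FALSE)
  if (is.matrix(gene_copies)) {
    sweep(gene_copies, 1, copy_numbers[taxa], "/")
  } else {
    gene_copies / copy_numbers[taxa]
  }
}

#' Fixed-total scaling of qPCR concentrations
#'
#' Per sample: relative abundance = concentration / total bacterial
#' concentration, then rescaled to a fixed total bacterial count
#' (default 1e7 per uL) so samples are comparable. Samples with zero or
#' missing total are excluded with a warning.
#'
#' @param otu_conc numeric matrix, taxa x samples.
#' @param total_bacterial_conc named numeric vector of per-sample total
#'   bacterial concentration (from a universal 16S assay).
#' @param target_total the fixed total to scale to (per uL).
#' @return matrix of adjusted concentrations with `kind` attribute
#'   "qpcr_relative"; excluded samples are dropped.
#' @export
normalize_to_total <- function(otu_conc, total_bacterial_conc,
                               target_total = 1e7) {
  samples <- colnames(otu_conc)
  tot <- total_bacterial_conc[samples]
  bad <- is.na(tot) | tot <= 0
  if (any(bad)) {
    warning("sample(s) with zero/missing total bacterial concentration ",
            "excluded: ", paste(samples[bad], collapse = ", "),
            call. = FALSE)
    otu_conc <- otu_conc[, !bad, drop = FALSE]
    tot <- tot[!bad]
  }
  out <- sweep(otu_conc, 2, tot, "/") * target_total
  attr(out, "kind") <- "qpcr_relative"
  out
}

#' Read the bundled 16S copy-number table
#'
#' A synthetic stand-in for a per-taxon 16S rRNA copy-number reference
#' (copies per genome); values are representative of the assayed taxa. Any
#' user table with columns `taxon` and `copy_number` can be supplied instead.
#'
#' @param path TSV with columns `taxon`, `copy_number`; default the bundled
#'   synthetic table.
#' @return named numeric vector taxon -> copies per genome.
#' @export
read_copy_numbers <- function(path = system.file("extdata",
                                                 "copy_numbers_synthetic.tsv",
                                                 package = "tricohort")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  setNames(tab$copy_number, tab$taxon)
}
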