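# Scoring and ranking candidate search models: mean pLDDT with the usual
# confidence bands, a coverage-weighted score that rewards hits spanning more
# of the target sequence, and per-domain summary reports.

plddt_bands <- c(very_low = 0, low = 50, confident = 70, very_high = 90)

#' Confidence band of a pLDDT value
#'
#' Band boundaries follow the AlphaFold colour-band convention:
#' below 50 `very_low`, 50-70 `low`, 70-90 `confident` (70 or more indicates
#' a high-confidence prediction), 90 and above `very_high`. Boundaries are
#' inclusive on the left.
#'
#' @param plddt pLDDT value(s) on the 0-100 scale.
#' @return Character band label(s).
#' @export
plddt_band <- function(plddt) {
  if (any(!is.finite(plddt)) || any(plddt < 0 | plddt > 100)) {
    mr_abort("pLDDT out of range")
  }
  labs <- names(plddt_bands)
  labs[findInterval(plddt, plddt_bands)]
}

#' Average pLDDT of a profile, with its confidence band
#'
#' @param profile A [confidence_profile()] carrying pLDDT (either scale).
#' @return A list with `mean_plddt` (0-100 scale) and `band`.
#' @export
average_plddt <- function(profile) {
  if (nrow(profile) == 0) mr_abort("no residues")
  v <- profile_plddt100(profile)
  m <- mean(v)
  list(mean_plddt = m, band = plddt_band(m))
}

#' Coverage-weighted confidence score
#'
#' Mean pLDDT scaled by the fraction of the target sequence the hit covers:
#' `sum(pLDDT_i) / target_length` on the 0-100 scale. A full-length hit
#' scores its mean pLDDT; shorter hits are down-weighted in proportion, so a
#' full-length model at pLDDT 60 outranks a half-length model at 90. This
#' follows the coverage-weighting idea behind MrParse's H-score without
#' claiming numerical equality with that published score.
#'
#' @param profile A [confidence_profile()] carrying pLDDT for the residues
#'   present in the hit.
#' @param target_length Length of the target sequence in residues
#'   (at least the profile length).
#' @return Score on the 0-100 scale.
#' @export
coverage_weighted_score <- function(profile, target_length) {
  if (nrow(profile) == 0) mr_abort("no residues")
  if (target_length < nrow(profile)) mr_abort("hit exceeds target length")
  sum(profile_plddt100(profile)) / target_length
}

#' Score a candidate search model
#'
#' @param model A [predicted_model].
#' @param profile Optional [confidence_profile()]; built from the model when
#'   `NULL`.
#' @param target_length Target sequence length in residues; defaults to the
#'   model's own residue count (coverage 1).
#' @return A `model_score` object: `mean_plddt`, `coverage`,
#'   `coverage_weighted`, `band`, `n_residues`.
#' @export
score_model <- function(model, profile = NULL, target_length = NULL) {
  profile <- profile %||% confidence_profile(model)
  target_length <- target_length %||% nrow(profile)
  avg <- average_plddt(profile)
  structure(
    list(
      mean_plddt = avg$mean_plddt,
      coverage = nrow(profile) / target_length,
      coverage_weighted = coverage_weighted_score(profile, target_length),
      band = avg$band,
      n_residues = nrow(profile)
    ),
    class = "model_score"
  )
}

#' @export
print.model_score <- function(x, ...) {
  cat(sprintf(
    "<model_score> mean pLDDT %.1f (%s), coverage %.2f, coverage-weighted %.1f over %d residues\n",
    x$mean_plddt, x$band, x$coverage, x$coverage_weighted, x$n_residues))
  invisible(x)
}

#' @method glance model_score
#' @export
glance.model_score <- function(x, ...) {
  tibble(mean_plddt = x$mean_plddt, coverage = x$coverage,
         coverage_weighted = x$coverage_weighted, band = x$band,
         n_residues = x$n_residues)
}

#' @method tidy model_score
#' @export
tidy.model_score <- function(x, ...) glance.model_score(x)

# Radius of gyration of a point set about its centroid.
radius_of_gyration <- function(xyz) {
  if (nrow(xyz) == 0) return(NA_real_)
  c0 <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, c0)^2)))
}

collapse_ranges <- function(chain, resno) {
  if (length(resno) == 0) return("")
  o <- order(match(chain, unique(chain)), resno)
  chain <- chain[o]; resno <- resno[o]
  brk <- c(TRUE, !(chain[-1] == chain[-length(chain)] &
                   resno[-1] == resno[-length(resno)] + 1))
  seg <- cumsum(brk)
  paste(vapply(split(seq_along(seg), seg), function(i) {
    sprintf("%s:%d-%d", chain[i[1]], resno[i[1]], resno[i[length(i)]])
  }, ""), collapse = ",")
}

#' Per-domain summary report of a partition
#'
#' One row per domain with its size, sequence ranges, mean confidence,
#' C-alpha radius of gyration and centroid, plus a final row summarizing the
#' residues excluded from the partition (if any).
#'
#' @param model A [predicted_model].
#' @param partition A `domain_partition` for the model.
#' @param profile Optional [confidence_profile()] aligned to the model; built
#'   from the model when `NULL`.
#' @return A tibble, one row per domain (`domain` is `NA` on the removed
#'   row).
#' @export
domain_report <- function(model, partition, profile = NULL) {
  validate_partition(partition, model)
  profile <- profile %||% confidence_profile(model)
  res <- residues(model)
  if (nrow(profile) != nrow(res)) mr_abort("length mismatch")
  groups <- c(sort(unique(partition$domain[!is.na(partition$domain)])),
              if (anyNA(partition$domain)) NA_integer_)
  rows <- map(groups, function(d) {
    sel <- if (is.na(d)) is.na(partition$domain) else
      !is.na(partition$domain) & partition$domain == d
    xyz <- as.matrix(res[sel & res$has_ca, c("ca_x", "ca_y", "ca_z")])
    cent <- if (nrow(xyz) > 0) colMeans(xyz) else rep(NA_real_, 3)
    tibble(
      domain = d,
      size = sum(sel),
      ranges = collapse_ranges(res$chain[sel], res$resno[sel]),
      mean_confidence = mean(profile$value[sel]),
      rg = radius_of_gyration(xyz),
      centroid_x = cent[1], centroid_y = cent[2], centroid_z = cent[3]
    )
  })
  bind_rows(rows)
}
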