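# Confidence handling: detect which metric the B column carries, convert it
# to crystallographic B factors, prune unreliable residues and clean up short
# disconnected segments.
#
# Metric kinds:
#   plddt100        pLDDT on the usual 0-100 scale (AlphaFold2, ESMFold)
#   plddt1          pLDDT rescaled to [0,1] (some pipelines)
#   rmsd_angstrom   per-residue estimated r.m.s.d. in Angstroms (RoseTTAFold)
#   bfactor_already genuine B factors; conversion is the identity

confidence_kinds <- c("plddt100", "plddt1", "rmsd_angstrom", "bfactor_already")

#' Detect the confidence metric stored in a value vector
#'
#' Applies the conventions of the common prediction programs: values all in
#' \[0,1\] are fractional pLDDT; values in \[0,100\] with at least 5% above 20
#' are pLDDT on the 0-100 scale; values all within \[0,20\] look like a
#' per-residue r.m.s.d. estimate in Angstroms; anything else is taken to be a
#' genuine B factor. An explicitly declared kind always wins.
#'
#' @param values Numeric vector of per-residue B-column values.
#' @param declared Optional kind (one of `r toString(confidence_kinds)`)
#'   overriding detection.
#' @return A single kind string.
#' @export
detect_confidence_kind <- function(values, declared = NULL) {
  if (!is.null(declared)) {
    declared <- match.arg(declared, confidence_kinds)
    return(declared)
  }
  if (length(values) == 0 || any(!is.finite(values))) {
    mr_abort("invalid confidence values")
  }
  if (any(values < 0)) mr_abort("invalid confidence values")
  if (all(values <= 1)) return("plddt1")
  if (all(values <= 100) && mean(values > 20) >= 0.05) return("plddt100")
  if (all(values <= 20)) return("rmsd_angstrom")
  "bfactor_already"
}

#' Build a per-residue confidence profile from a model
#'
#' @param model A [predicted_model].
#' @param kind Optional declared metric kind; detected from the values when
#'   `NULL`.
#' @return A `confidence_profile` tibble (`res_index`, `chain`, `resno`,
#'   `icode`, `value`) with the kind stored in the `"kind"` attribute.
#' @export
confidence_profile <- function(model, kind = NULL) {
  res <- residues(model)
  kind <- detect_confidence_kind(res$raw_confidence, declared = kind)
  validate_profile_values(res$raw_confidence, kind)
  structure(
    res[, c("res_index", "chain", "resno", "icode")] |>
      mutate(value = res$raw_confidence),
    kind = kind,
    class = c("confidence_profile", class(tibble()))
  )
}

profile_kind <- function(profile) attr(profile, "kind")

validate_profile_values <- function(values, kind) {
  if (length(values) == 0) mr_abort("no residues")
  if (any(!is.finite(values)) || any(values < 0)) {
    mr_abort("invalid confidence values")
  }
  if (kind == "plddt1" && any(values > 1)) mr_abort("invalid confidence values")
  if (kind == "plddt100" && any(values > 100)) mr_abort("invalid confidence values")
  invisible(values)
}

# pLDDT on the 0-100 scale regardless of the stored scale.
profile_plddt100 <- function(profile) {
  kind <- profile_kind(profile)
  switch(kind,
    plddt100 = profile$value,
    plddt1 = profile$value * 100,
    mr_abort("threshold kind mismatch: profile does not carry pLDDT")
  )
}

#' Conversion parameters for pLDDT / r.m.s.d. to B factors
#'
#' The pLDDT-to-r.m.s.d. curve is
#' `rmsd(p) = min(rmsd_cap, lddt_scale * exp(lddt_slope * (lddt_midpoint - p)))`
#' with `p` the fractional pLDDT, so a residue at the 0.7 midpoint maps to
#' `lddt_scale` Angstroms. The r.m.s.d. then becomes an isotropic B factor via
#' `B = (8 pi^2 / 3) * rmsd^2`.
#'
#' @param lddt_midpoint Fractional pLDDT mapped to `lddt_scale` (default 0.7).
#' @param lddt_scale r.m.s.d. in Angstroms at the midpoint (default 1.5).
#' @param lddt_slope Dimensionless steepness of the exponential (default 4).
#' @param rmsd_cap Largest r.m.s.d. in Angstroms the curve may return
#'   (default 20), preventing absurd B factors as pLDDT approaches 0.
#' @return A `conversion_params` list.
#' @export
conversion_params <- function(lddt_midpoint = 0.7, lddt_scale = 1.5,
                              lddt_slope = 4, rmsd_cap = 20) {
  p <- list(lddt_midpoint = lddt_midpoint, lddt_scale = lddt_scale,
            lddt_slope = lddt_slope, rmsd_cap = rmsd_cap)
  if (any(unlist(p) <= 0)) mr_abort("conversion parameters must be positive")
  if (rmsd_cap < lddt_scale) mr_abort("rmsd_cap must be at least lddt_scale")
  structure(p, class = "conversion_params")
}

#' Convert fractional pLDDT to an estimated r.m.s.d.
#'
#' @param p Fractional pLDDT in \[0,1\] (vectorized).
#' @param params A [conversion_params()] record.
#' @return Estimated r.m.s.d. in Angstroms, capped at `params$rmsd_cap`.
#' @export
plddt_to_rmsd <- function(p, params = conversion_params()) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) mr_abort("pLDDT out of range")
  pmin(params$rmsd_cap,
       params$lddt_scale * exp(params$lddt_slope * (params$lddt_midpoint - p)))
}

#' Convert an estimated r.m.s.d. to an isotropic B factor
#'
#' `B = (8 pi^2 / 3) * rmsd^2` (Angstroms squared).
#'
#' @param r r.m.s.d. in Angstroms (vectorized, non-negative).
#' @return B factor in Angstroms squared.
#' @export
rmsd_to_bfactor <- function(r) {
  if (any(!is.finite(r)) || any(r < 0)) mr_abort("invalid rmsd")
  (8 * pi^2 / 3) * r^2
}

#' Inverse of [rmsd_to_bfactor()]
#'
#' @param b B factor in Angstroms squared (non-negative).
#' @return r.m.s.d. in Angstroms.
#' @export
bfactor_to_rmsd <- function(b) {
  if (any(!is.finite(b)) || any(b < 0)) mr_abort("invalid rmsd")
  sqrt(3 * b / (8 * pi^2))
}

#' Replace the confidence column of a model by converted B factors
#'
#' pLDDT profiles (either scale) go through [plddt_to_rmsd()] then
#' [rmsd_to_bfactor()]; r.m.s.d. profiles go straight to [rmsd_to_bfactor()];
#' a `bfactor_already` profile leaves the model unchanged. Every atom of a
#' residue receives the residue-level converted B.
#'
#' @param model A [predicted_model].
#' @param profile A [confidence_profile()] aligned to the model; built from
#'   the model when `NULL`.
#' @param params A [conversion_params()] record.
#' @return The model with converted B factors and a conversion note appended
#'   to its source tag.
#' @export
convert_to_bfactors <- function(model, profile = NULL,
                                params = conversion_params()) {
  profile <- profile %||% confidence_profile(model)
  res_idx <- residue_index_of_atoms(model)
  if (nrow(profile) != max(res_idx)) {
    mr_abort("profile/model length mismatch")
  }
  kind <- profile_kind(profile)
  if (kind == "bfactor_already") return(model)
  rmsd <- switch(kind,
    plddt100 = plddt_to_rmsd(profile$value / 100, params),
    plddt1 = plddt_to_rmsd(profile$value, params),
    rmsd_angstrom = pmin(profile$value, params$rmsd_cap)
  )
  b_res <- rmsd_to_bfactor(rmsd)
  model$b <- b_res[res_idx]
  append_source_tag(model, paste0("b_converted:", kind))
}

#' Remove residues below a pLDDT confidence threshold
#'
#' Retains exactly the residues whose pLDDT is greater than or equal to the
#' threshold ("70 or better" keeps a residue at exactly 70). The profile must
#' carry pLDDT; for an r.m.s.d. profile an explicit Angstrom ceiling must be
#' given instead, and residues at or below it are kept.
#'
#' @param model A [predicted_model].
#' @param profile A [confidence_profile()]; built from the model when `NULL`
#'   (use this before B-factor conversion, or pass the pre-conversion
#'   profile).
#' @param threshold pLDDT cutoff on the 0-100 scale (default 70).
#' @param rmsd_threshold Optional r.m.s.d. ceiling in Angstroms, required when
#'   the profile kind is `rmsd_angstrom`.
#' @return The pruned model (residue order preserved; idempotent).
#' @export
prune_low_confidence <- function(model, profile = NULL, threshold = 70,
                                 rmsd_threshold = NULL) {
  if (nrow(model) == 0) return(model)
  profile <- profile %||% confidence_profile(model)
  res_idx <- residue_index_of_atoms(model)
  if (nrow(profile) != max(res_idx)) mr_abort("profile/model length mismatch")
  kind <- profile_kind(profile)
  keep <- if (kind %in% c("plddt100", "plddt1")) {
    profile_plddt100(profile) >= threshold
  } else if (kind == "rmsd_angstrom") {
    if (is.null(rmsd_threshold)) {
      mr_abort("threshold kind mismatch: r.m.s.d. profile needs an explicit rmsd_threshold")
    }
    profile$value <= rmsd_threshold
  } else {
    mr_abort("threshold kind mismatch: profile does not carry pLDDT")
  }
  subset_model(model, which(keep))
}

# Subset a model to the residues whose res_index is in `res_keep`.
subset_model <- function(model, res_keep) {
  res_idx <- residue_index_of_atoms(model)
  out <- model[res_idx %in% res_keep, , drop = FALSE]
  attributes(out)$source_tag <- attr(model, "source_tag")
  attributes(out)$title <- attr(model, "title")
  class(out) <- class(model)
  out
}

# Contiguous segments: same chain, consecutive author numbering and a bounded
# CA-CA step. Returns the per-residue segment id (in residue order).
segment_ids <- function(res, break_distance = 4.5) {
  n <- nrow(res)
  if (n == 0) return(integer(0))
  new_seg <- logical(n)
  new_seg[1] <- TRUE
  if (n > 1) {
    same_chain <- res$chain[-1] == res$chain[-n]
    consec <- res$resno[-1] == res$resno[-n] + 1
    d <- sqrt((res$ca_x[-1] - res$ca_x[-n])^2 +
              (res$ca_y[-1] - res$ca_y[-n])^2 +
              (res$ca_z[-1] - res$ca_z[-n])^2)
    close_enough <- !is.na(d) & d <= break_distance
    # residues without CA cannot be checked geometrically; numbering decides
    close_enough[is.na(d)] <- TRUE
    new_seg[-1] <- !(same_chain & consec & close_enough)
  }
  cumsum(new_seg)
}

#' Drop short disconnected segments from a model
#'
#' Residues are grouped into contiguous segments (same chain, consecutive
#' author numbering, successive C-alpha distance at most `break_distance`);
#' segments shorter than `min_len` residues are removed. This eliminates the
#' unstructured scraps and disconnected stubs that survive confidence pruning
#' but carry no molecular-replacement signal.
#'
#' @param model A [predicted_model].
#' @param min_len Minimum segment length in residues (default 3).
#' @param break_distance C-alpha to C-alpha distance in Angstroms above which
#'   the chain is considered broken (default 4.5; the virtual bond is 3.8).
#' @return The cleaned model (possibly empty of some segments).
#' @export
remove_short_segments <- function(model, min_len = 3, break_distance = 4.5) {
  res <- residues(model)
  seg <- segment_ids(res, break_distance = break_distance)
  seg_len <- tabulate(seg)
  keep <- res$res_index[seg_len[seg] >= min_len]
  subset_model(model, keep)
}

#' Trim a model to residue ranges of the target
#'
#' Retains exactly the residues inside the union of the given inclusive
#' ranges. Ranges are typically produced by [align_to_target()].
#'
#' @param model A [predicted_model].
#' @param keep Data frame with columns `chain`, `start`, `end` (inclusive
#'   author residue numbers). An empty frame yields an empty selection.
#' @return The trimmed model.
#' @export
trim_to_target <- function(model, keep) {
  keep <- as_tibble(keep)
  if (nrow(keep) > 0) {
    if (!all(c("chain", "start", "end") %in% names(keep))) {
      mr_abort("malformed input: keep needs chain/start/end columns")
    }
    if (any(keep$start > keep$end)) {
      mr_abort("malformed input: range start exceeds end")
    }
    unknown <- setdiff(keep$chain, unique(model$chain))
    if (length(unknown) > 0) {
      mr_abort(paste0("unknown chain: ", paste(unknown, collapse = ", ")))
    }
  }
  res <- residues(model)
  in_any <- rep(FALSE, nrow(res))
  for (i in seq_len(nrow(keep))) {
    in_any <- in_any | (res$chain == keep$chain[i] &
                        res$resno >= keep$start[i] &
                        res$resno <= keep$end[i])
  }
  subset_model(model, res$res_index[in_any])
}

#' Residue ranges of a model aligned to a target sequence
#'
#' Globally aligns the model's one-letter sequence to a target sequence
#' (Needleman-Wunsch, BLOSUM62, affine gaps) and returns the model residue
#' ranges whose positions align to target residues, suitable for
#' [trim_to_target()].
#'
#' @param model A [predicted_model].
#' @param target Target sequence: a character string, an
#'   `Biostrings::AAString`, or a path to a FASTA file (first record used).
#' @param gap_opening,gap_extension Affine gap penalties (defaults 10 / 0.5).
#' @return A tibble of `chain`, `start`, `end` ranges.
#' @export
align_to_target <- function(model, target, gap_opening = 10,
                            gap_extension = 0.5) {
  res <- residues(model)
  if (nrow(res) == 0) mr_abort("no residues")
  model_seq <- paste(bio3d::aa321(res$resid), collapse = "")
  target_seq <- read_target_sequence(target)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(model_seq),
    subject = Biostrings::AAString(target_seq),
    type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  pi <- cumsum(p != "-")
  keep_pos <- pi[p != "-" & s != "-"]
  if (length(keep_pos) == 0) return(tibble(chain = character(), start = integer(), end = integer()))
  kept <- res[res$res_index %in% keep_pos, ]
  seg <- cumsum(c(TRUE, !(kept$chain[-1] == kept$chain[-nrow(kept)] &
                          kept$resno[-1] == kept$resno[-nrow(kept)] + 1)))
  kept |>
    mutate(seg = seg) |>
    group_by(seg) |>
    summarise(chain = first(.data$chain), start = min(.data$resno),
              end = max(.data$resno), .groups = "drop") |>
    select("chain", "start", "end")
}

read_target_sequence <- function(target) {
  if (inherits(target, "AAString") || inherits(target, "AAStringSet")) {
    return(as.character(target)[[1]])
  }
  if (is.character(target) && length(target) == 1 && file.exists(target)) {
    set <- Biostrings::readAAStringSet(target)
    if (length(set) == 0) mr_abort("no residues")
    return(as.character(set[[1]]))
  }
  if (is.character(target) && length(target) == 1) return(target)
  mr_abort("malformed input: unsupported target sequence")
}
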