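# End-to-end pipeline runners behind the command-line interface. Each run_*
# function is an ordinary library function returning the artifacts it wrote
# plus a machine-readable report; the exec/mrprep script is a thin argument
# parser over them. On error no partial outputs are left behind: files are
# staged in a temporary directory and moved into place only on success.

stage_outputs <- function(writer) {
  stage <- tempfile("mrprep-stage-")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE))
  paths <- writer(stage)
  final <- character(0)
  for (p in paths) {
    dest <- file.path(dirname(p$dest), basename(p$dest))
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    file.copy(p$staged, dest, overwrite = TRUE)
    final <- c(final, dest)
  }
  final
}

write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}

model_ext <- function(format) if (format == "pdb") ".pdb" else ".cif"

#' Run the full preparation pipeline on a predicted model
#'
#' Detect the confidence metric, convert the B column to crystallographic B
#' factors, prune residues below the pLDDT threshold, drop short disconnected
#' segments, and write the prepared search model plus a JSON report of what
#' was done.
#'
#' @param input Path to the input model (PDB or mmCIF).
#' @param out_prefix Output path prefix; `<prefix>_prepared.pdb` (or `.cif`)
#'   and `<prefix>_report.json` are written.
#' @param threshold pLDDT inclusion cutoff on the 0-100 scale (default 70).
#' @param prune Set `FALSE` to skip confidence pruning.
#' @param min_segment Minimum contiguous segment length kept (default 3).
#' @param kind Confidence kind: `"auto"` or one of
#'   `plddt100`, `plddt1`, `rmsd_angstrom`, `bfactor_already`.
#' @param rmsd_threshold Explicit r.m.s.d. ceiling in Angstroms, required to
#'   prune when the profile is an r.m.s.d. estimate.
#' @param params A [conversion_params()] record.
#' @param out_format `"pdb"` or `"mmcif"`.
#' @return Invisibly, a list with `paths` (files written) and `report`.
#' @export
run_prepare <- function(input, out_prefix, threshold = 70, prune = TRUE,
                        min_segment = 3, kind = "auto", rmsd_threshold = NULL,
                        params = conversion_params(),
                        out_format = c("pdb", "mmcif")) {
  out_format <- match.arg(out_format)
  declared <- if (identical(kind, "auto")) NULL else kind
  model <- read_model(input)
  profile <- confidence_profile(model, kind = declared)
  n_in <- nrow(profile)
  converted <- convert_to_bfactors(model, profile, params = params)
  pruned <- if (prune) {
    prune_low_confidence(converted, profile, threshold = threshold,
                         rmsd_threshold = rmsd_threshold)
  } else converted
  n_after_prune <- nrow(residues(pruned))
  cleaned <- if (nrow(pruned) > 0) {
    remove_short_segments(pruned, min_len = min_segment)
  } else pruned
  if (nrow(cleaned) == 0) mr_abort("no atoms: every residue was removed")
  n_final <- nrow(residues(cleaned))
  score <- if (profile_kind(profile) %in% c("plddt100", "plddt1")) {
    res_all <- residues(model)
    res_kept <- residues(cleaned)
    orig_idx <- match(paste(res_kept$chain, res_kept$resno, res_kept$icode),
                      paste(res_all$chain, res_all$resno, res_all$icode))
    kept <- profile[orig_idx, ]
    attr(kept, "kind") <- profile_kind(profile)
    class(kept) <- class(profile)
    glance(score_model(cleaned, profile = kept, target_length = n_in))
  } else NULL
  report <- list(
    tool = "mrprep prepare",
    input = as.character(input)[1],
    kind_detected = profile_kind(profile),
    parameters = c(list(threshold = threshold, prune = prune,
                        min_segment = min_segment, out_format = out_format),
                   unclass(params)),
    n_residues_input = n_in,
    n_removed_prune = n_in - n_after_prune,
    n_removed_segments = n_after_prune - n_final,
    n_residues_output = n_final,
    score = if (is.null(score)) NULL else as.list(score)
  )
  model_path <- paste0(out_prefix, "_prepared", model_ext(out_format))
  report_path <- paste0(out_prefix, "_report.json")
  paths <- stage_outputs(function(stage) {
    mp <- file.path(stage, basename(model_path))
    rp <- file.path(stage, basename(report_path))
    write_model(cleaned, mp, format = out_format)
    write_report(report, rp)
    list(list(staged = mp, dest = model_path),
         list(staged = rp, dest = report_path))
  })
  invisible(list(paths = paths, report = report, model = cleaned))
}

#' Run the model-splitting ("slice") pipeline
#'
#' Splits a prepared model into domain-like search models and writes one
#' coordinate file per domain plus a JSON partition report. With
#' `sweep = TRUE` the k = 1, 2, 3 coordinate sweeps are each written to their
#' own subdirectory.
#'
#' @param input Path to the input model (PDB or mmCIF).
#' @param out_prefix Output path prefix.
#' @param method `"coords"` or `"pae"`.
#' @param n_clusters Number of clusters for `method = "coords"` (default 2).
#' @param sweep If `TRUE`, write the k = 1..3 coordinate sweep instead of a
#'   single split.
#' @param pae Path to a PAE JSON file (required for `method = "pae"`).
#' @param min_domain Smallest allowed domain size in residues (default 20).
#' @param out_format `"pdb"` or `"mmcif"`.
#' @param ... Further arguments to [split_by_coordinates()] or
#'   [split_by_pae()].
#' @return Invisibly, a list with `paths`, `report` and `partitions`.
#' @export
run_slice <- function(input, out_prefix, method = c("coords", "pae"),
                      n_clusters = 2, sweep = FALSE, pae = NULL,
                      min_domain = 20, out_format = c("pdb", "mmcif"), ...) {
  method <- match.arg(method)
  out_format <- match.arg(out_format)
  model <- read_model(input)
  profile <- confidence_profile(model)
  if (method == "pae" && is.null(pae)) {
    mr_abort("malformed input: method 'pae' requires a PAE JSON file")
  }
  partitions <- if (sweep) {
    default_split_sweep(model, min_domain = min_domain, ...)
  } else if (method == "coords") {
    list(split_by_coordinates(model, n_clusters = n_clusters,
                              min_domain = min_domain, ...))
  } else {
    list(split_by_pae(model, read_pae_json(pae), min_domain = min_domain, ...))
  }
  part_report <- function(part) {
    list(
      method = attr(part, "method"),
      params = attr(part, "params"),
      n_domains = n_domains(part),
      domains = lapply(seq_len(n_domains(part)), function(d) {
        sel <- !is.na(part$domain) & part$domain == d
        list(domain = d, size = sum(sel),
             mean_confidence = mean(profile$value[part$res_index[sel]]))
      }),
      labels = ifelse(is.na(part$domain), "removed", as.character(part$domain))
    )
  }
  report <- list(
    tool = "mrprep slice",
    input = as.character(input)[1],
    sweep = sweep,
    n_residues_input = nrow(profile),
    partitions = lapply(partitions, part_report)
  )
  paths <- stage_outputs(function(stage) {
    out <- list()
    for (pi in seq_along(partitions)) {
      part <- partitions[[pi]]
      sub <- if (sweep) sprintf("k%d", pi) else ""
      models <- extract_search_models(model, part)
      for (d in seq_along(models)) {
        fname <- sprintf("%s_domain_%d%s", basename(out_prefix), d,
                         model_ext(out_format))
        sdir <- file.path(stage, if (nzchar(sub)) sub else ".")
        dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
        sp <- file.path(sdir, fname)
        write_model(models[[d]], sp, format = out_format)
        ddir <- if (nzchar(sub)) file.path(dirname(out_prefix), sub) else
          dirname(out_prefix)
        out <- c(out, list(list(staged = sp, dest = file.path(ddir, fname))))
      }
    }
    rp <- file.path(stage, paste0(basename(out_prefix), "_partition.json"))
    write_report(report, rp)
    c(out, list(list(staged = rp,
                     dest = paste0(out_prefix, "_partition.json"))))
  })
  invisible(list(paths = paths, report = report, partitions = partitions))
}

#' Score a candidate model
#'
#' @param input Path to the model file.
#' @param target Optional target FASTA path (its first sequence's length sets
#'   the coverage denominator).
#' @param target_length Optional explicit target length (overrides `target`).
#' @param out Optional path for a JSON score record.
#' @return Invisibly, the `model_score`.
#' @export
run_score <- function(input, target = NULL, target_length = NULL, out = NULL) {
  model <- read_model(input)
  profile <- confidence_profile(model)
  if (is.null(target_length) && !is.null(target)) {
    target_length <- nchar(read_target_sequence(target))
  }
  score <- score_model(model, profile, target_length = target_length)
  if (!is.null(out)) {
    write_report(c(list(tool = "mrprep score", input = as.character(input)[1]),
                   unclass(score)), out)
  }
  invisible(score)
}

#' Write a synthetic fixture set to disk
#'
#' Writes the model (PDB), the PAE matrix (JSON, chosen dialect) and the
#' planted truth labels (JSON) for a [synthetic_spec()].
#'
#' @param spec A [synthetic_spec()].
#' @param out_prefix Output path prefix.
#' @param dialect PAE JSON dialect (see [write_pae_json()]).
#' @return Invisibly, the vector of paths written.
#' @export
run_fixture <- function(spec, out_prefix,
                        dialect = c("afdb_nested", "afdb_flat", "pae")) {
  dialect <- match.arg(dialect)
  fx <- generate_model(spec)
  pae <- generate_pae(spec)
  paths <- stage_outputs(function(stage) {
    mp <- file.path(stage, paste0(basename(out_prefix), "_model.pdb"))
    pp <- file.path(stage, paste0(basename(out_prefix), "_pae.json"))
    tp <- file.path(stage, paste0(basename(out_prefix), "_truth.json"))
    write_model(fx$model, mp, format = "pdb")
    write_pae_json(pae, pp, dialect = dialect)
    write_report(list(spec = unclass(spec),
                      labels = fx$truth$label), tp)
    list(list(staged = mp, dest = paste0(out_prefix, "_model.pdb")),
         list(staged = pp, dest = paste0(out_prefix, "_pae.json")),
         list(staged = tp, dest = paste0(out_prefix, "_truth.json")))
  })
  invisible(paths)
}
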