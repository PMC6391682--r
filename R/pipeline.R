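#' Validate a run manifest
#'
#' Checks a manifest (YAML path or list) before any work: unique
#' sample ids, every group non-empty, referenced files readable, and
#' parameter ranges. The manifest schema is:
#' \preformatted{
#' reference:
#'   genome: genome.fa
#'   plasmids: [pIR.fa]          # optional
#' annotations:
#'   gff3: annotations.gff3      # optional
#'   repeat_bed: repeats.bed     # optional
#' hairpins: [mosir.yaml]        # optional hairpin spec files
#' params:                       # optional overrides
#'   rpm_threshold: 3
#'   join_distance: 50
#' samples:
#'   - {sample_id: A1, group: A, replicate: 1, fastq: A1.fq}
#'   - {sample_id: B1, group: B, replicate: 1, sam: B1.sam}
#' }
#'
#' @param manifest path to a YAML manifest, or an equivalent list.
#' @return A character vector of problems (empty when valid).
#' @export
validate_manifest <- function(manifest) {
  m <- if (is.character(manifest)) yaml::read_yaml(manifest) else manifest
  problems <- character()
  note <- function(...) problems <<- c(problems, paste0(...))
  if (is.null(m$samples) || length(m$samples) == 0L)
    note("manifest has no samples")
  ids <- vapply(m$samples, function(s) s$sample_id %||% "", character(1))
  if (anyDuplicated(ids))
    note("duplicate sample_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(ids))) note("every sample needs a sample_id")
  for (s in m$samples) {
    if (is.null(s$group)) note("sample ", s$sample_id, " has no group")
    path <- s$fastq %||% s$sam
    if (is.null(path))
      note("sample ", s$sample_id, " has neither fastq nor sam")
    else if (!file.exists(path))
      note("sample ", s$sample_id, ": file not found: ", path)
  }
  if (is.null(m$reference$genome))
    note("manifest needs reference: genome")
  else if (!file.exists(m$reference$genome))
    note("reference genome not found: ", m$reference$genome)
  for (p in c(m$reference$plasmids, m$annotations$gff3,
              m$annotations$repeat_bed, m$hairpins))
    if (!is.null(p) && !file.exists(p)) note("file not found: ", p)
  pp <- m$params
  if (!is.null(pp$rpm_threshold) && pp$rpm_threshold <= 0)
    note("rpm_threshold must be > 0")
  if (!is.null(pp$join_distance) && pp$join_distance < 0)
    note("join_distance must be >= 0")
  problems
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full small RNA pipeline from a manifest
#'
#' Orchestrates, per sample, trimming (FASTQ inputs only) and
#' perfect-match alignment (or SAM import); then per-group cluster
#' calling with all-replicate intersection, cross-group merging with
#' per-sample RPMs, hierarchical annotation, and, for each hairpin
#' spec, length abundance, arm density and phasing tables. All outputs
#' are deterministic TSV/BED files plus a YAML run log recording every
#' parameter and per-stage read counts.
#'
#' @param manifest path to a YAML manifest, or an equivalent list (see
#'   [validate_manifest()]).
#' @param out_dir output directory (created).
#' @return Invisibly, a list with the merged annotated clusters, the
#'   per-sample libraries, and the run log.
#' @export
run_pipeline <- function(manifest, out_dir) {
  m <- if (is.character(manifest)) yaml::read_yaml(manifest) else manifest
  problems <- validate_manifest(m)
  if (length(problems))
    stop("invalid manifest:\n  ", paste(problems, collapse = "\n  "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(params = m$params %||% list(), stages = list())

  pp <- m$params %||% list()
  params <- cluster_params(
    rpm_threshold = pp$rpm_threshold %||% 3,
    join_distance = pp$join_distance %||% 50L)
  tcfg <- trim_config()

  ref <- build_reference(m$reference$genome, m$reference$plasmids)
  ann <- read_annotations(gff3 = m$annotations$gff3,
                          repeat_bed = m$annotations$repeat_bed)

  libs <- list()
  for (s in m$samples) {
    sid <- s$sample_id
    step <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stop("pipeline stage '", what, "' failed for sample ", sid, ": ",
             conditionMessage(e), call. = FALSE))
    }
    if (!is.null(s$fastq)) {
      tr <- step("trim", trim_library(s$fastq, tcfg))
      lib <- step("align", align_library(
        tr$reads, ref, sample_id = sid, group = s$group,
        replicate = s$replicate %||% 1L))
      log$stages[[sid]] <- c(as.list(tr$report),
                             n_mapped = lib$n_mapped)
    } else {
      imp <- step("import_sam", import_sam(s$sam, ref))
      lib <- small_rna_library(imp$alignments, sample_id = sid,
                               group = s$group,
                               replicate = s$replicate %||% 1L)
      log$stages[[sid]] <- c(as.list(imp$report), trim = "skipped")
    }
    libs[[sid]] <- lib
  }

  # per-group cluster calling + replicate intersection
  groups <- split(libs, vapply(libs, `[[`, "", "group"))
  group_clusters <- lapply(groups, function(gl) {
    per_rep <- lapply(gl, call_sample_clusters, params = params)
    intersect_replicates(unname(per_rep))
  })

  merged <- merge_between_samples(group_clusters, libraries = libs,
                                  lengths = params$read_lengths)
  merged <- annotate_clusters(merged, ann)
  export_clusters(merged,
                  bed_path = file.path(out_dir, "clusters.bed"),
                  tsv_path = file.path(out_dir, "clusters.tsv"))

  # hairpin analyses per spec per sample
  for (hpath in m$hairpins %||% list()) {
    hp <- read_hairpin_spec(hpath)
    tag <- tools::file_path_sans_ext(basename(hpath))
    for (sid in names(libs)) {
      lib <- libs[[sid]]
      utils::write.table(
        hairpin_length_abundance(lib, hp),
        file.path(out_dir, sprintf("%s_%s_lengths.tsv", tag, sid)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        arm_density(lib, hp),
        file.path(out_dir, sprintf("%s_%s_density.tsv", tag, sid)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      ph <- phasing_profile(lib, hp)
      utils::write.table(
        data.frame(register = seq_len(ph$period),
                   proportion = as.numeric(ph$proportions)),
        file.path(out_dir, sprintf("%s_%s_phasing.tsv", tag, sid)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  log$denominators <- lapply(libs, `[[`, "denominator")
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  invisible(list(clusters = merged, libraries = libs, log = log))
}
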