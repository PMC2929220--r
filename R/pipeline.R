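# End-to-end orchestration of the three analyses (identity/phylogeny, domain
# divergence, conservation mapping) with a JSON manifest of deterministic
# outputs.

#' Run the full comparative analysis pipeline
#'
#' Reads a protein family (either unaligned FASTA, aligned FASTA, or a
#' Clustal `.aln`), and writes, under `out_dir`:
#'
#' 1. `identity.tsv` and `identity.phylip` -- the percent-identity matrix;
#' 2. `tree.nwk` -- the whole-protein NJ tree (rooted at `outgroup` if
#'    given);
#' 3. `domain_<name>.nwk` -- one NJ tree per requested domain;
#' 4. `domain_divergence.tsv` -- outgroup-to-taxon divergence per domain;
#' 5. `conservation.tsv` -- per-column conservation classes at the
#'    receptor-ligand contact columns (when a structure is supplied);
#' 6. `manifest.json` -- tool version, parameters, input checksums and the
#'    output listing.
#'
#' Stages without the needed inputs (no domain map, no structure) are
#' omitted from the manifest rather than failing.
#'
#' @param config Named list. Recognised fields: `seqs` (unaligned FASTA) or
#'   `msa` (aligned FASTA) or `aln` (Clustal); `model`
#'   (`"jtt"`/`"dayhoff"`/`"poisson"`); `convention` (identity convention);
#'   `outgroup`; `domain_tsv`; `domains` (list of domain selections, default
#'   all map entries); `refs` (named character vector of reference leaf
#'   labels for subfamily classification); `structure` (PDB path);
#'   `receptor_chain`, `ligand_chain` (default auto-detected), `cutoff`
#'   (default 4.0); `structure_member` (family row matching the structure);
#'   `out_dir` (required).
#' @return The manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- list()
  need_file <- function(path, what) {
    if (!file.exists(path)) stop(what, " input missing: ", path)
    inputs[[what]] <<- unname(tools::md5sum(path))
    path
  }
  # --- family alignment ---
  if (!is.null(config$msa)) {
    aln <- read_msa_fasta(need_file(config$msa, "msa"))
  } else if (!is.null(config$aln)) {
    aln <- read_clustal(need_file(config$aln, "aln"))
  } else if (!is.null(config$seqs)) {
    seqs <- read_fasta(need_file(config$seqs, "seqs"), type = "protein")
    aln <- progressive_align(seqs)
  } else stop("config must name one of: seqs, msa, aln")
  model <- substitution_model(config$model %||% "jtt")
  convention <- config$convention %||% "aligned_columns"
  outputs <- character(0)
  emit <- function(name) {
    outputs <<- c(outputs, name)
    file.path(out_dir, name)
  }
  # --- identity matrix ---
  idm <- identity_matrix(aln, convention)
  tab <- data.frame(id = rownames(idm), round(unclass(idm), 1),
                    check.names = FALSE)
  write.table(tab, emit("identity.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_phylip_matrix(unclass(idm), emit("identity.phylip"))
  # --- whole-protein tree ---
  D <- distance_matrix(aln, model)
  tree <- neighbor_joining(D)
  if (!is.null(config$outgroup)) tree <- root_at(tree, config$outgroup)
  write_newick(tree, emit("tree.nwk"))
  classification <- NULL
  if (!is.null(config$refs)) {
    if (is.null(config$outgroup))
      stop("subfamily classification needs config$outgroup")
    classification <- classify_subfamilies(tree, config$refs)
    write.table(data.frame(taxon = names(classification),
                           subfamily = unname(classification)),
                emit("subfamilies.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  # --- domain divergence ---
  if (!is.null(config$domain_tsv) && !is.null(config$outgroup)) {
    dmap <- read_domain_map(need_file(config$domain_tsv, "domain_tsv"))
    domains <- config$domains %||%
      as.list(setNames(dmap$entries$domain, dmap$entries$domain))
    div <- domain_divergence(aln, dmap, domains, model, config$outgroup)
    write.table(div, emit("domain_divergence.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (dn in names(domains)) {
      cols <- domain_columns(aln, dmap, domains[[dn]])
      dtree <- root_at(neighbor_joining(
        distance_matrix(slice_msa(aln, cols), model),
        clamp_negative = TRUE), config$outgroup)
      write_newick(dtree, emit(paste0("domain_", gsub("\\W", "_", dn),
                                      ".nwk")))
    }
  }
  # --- conservation mapping ---
  if (!is.null(config$structure)) {
    s <- read_structure(need_file(config$structure, "structure"))
    chains <- auto_chains(s)
    receptor <- config$receptor_chain %||% chains$receptor
    ligand <- config$ligand_chain %||% chains$ligand
    cutoff <- config$cutoff %||% 4.0
    member <- config$structure_member %||%
      stop("config$structure_member is required with a structure")
    contacts <- find_contacts(s, receptor, ligand, cutoff)
    s_seq <- structure_chain_sequence(s, receptor)
    smap <- map_structure_to_family(s_seq, aln, member)
    seq_idx <- contacts$resnum - s_seq$numbering_origin + 1L
    cols <- smap[seq_idx[seq_idx >= 1 & seq_idx <= length(smap)]]
    cols <- cols[!is.na(cols)]
    cons <- classify_conservation(aln, cols)
    rep_tab <- cbind(contact_resnum = contacts$resnum[match(
      cols, smap[contacts$resnum - s_seq$numbering_origin + 1L])],
      cons$records)
    write.table(rep_tab, emit("conservation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    tool = "karyofam",
    version = as.character(utils::packageVersion("karyofam")),
    parameters = list(model = model$name, convention = convention,
                      outgroup = config$outgroup,
                      cutoff = config$cutoff %||% 4.0),
    inputs = inputs,
    outputs = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
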