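# End-to-end analysis run: read the ensemble, build the alignment,
# superpose, compute Cartesian and dihedral statistics, cluster, and write
# a deterministic result directory of plain-text tables plus a JSON
# summary.

#' Run the full ensemble analysis
#'
#' Orchestrates the pipeline on an ensemble described by a Structure list.
#' Stages are optional: clustering implies the dihedral stage, and the
#' Cartesian stage implies superposition (auto-enabled with a warning).
#' All outputs are deterministic: repeated runs on the same inputs are
#' byte-identical.
#'
#' @param structure_list path to (or text of) a Structure list; see
#'   [parse_structure_list()].
#' @param pdb_dir directory holding `<basename>.pdb` files.
#' @param out_dir output directory (created if needed).
#' @param positions optional path to (or text of) a Position list.
#' @param alignment `"numbering"` (default) or the path of an aligned
#'   FASTA / CLUSTAL file.
#' @param superpose,cartesian,dihedral,cluster stage switches.
#' @param reference reference structure label for superposition; default
#'   the first structure.
#' @param radius cluster radius in degrees (default 60), the minimum
#'   distance allowed between flat clusters.
#' @param first_position number of the first alignment position.
#' @param atom_set superposition atom set, `"backbone"` or `"calpha"`.
#' @param aggregation pairwise dihedral distance aggregation
#'   (`"mean"`, `"rms"`, `"max"`).
#' @return the run summary (also written as `summary.json`), invisibly:
#'   parameters, per-stage counts, output file names and collected
#'   warnings.
#' @export
run_analysis <- function(structure_list, pdb_dir, out_dir,
                         positions = NULL, alignment = "numbering",
                         superpose = TRUE, cartesian = TRUE,
                         dihedral = TRUE, cluster = TRUE,
                         reference = NULL, radius = 60,
                         first_position = 1L,
                         atom_set = c("backbone", "calpha"),
                         aggregation = c("mean", "rms", "max")) {
  atom_set <- match.arg(atom_set)
  aggregation <- match.arg(aggregation)
  warnings <- character()
  note <- function(...) warnings <<- c(warnings, paste0(...))
  if (cluster && !dihedral) {
    note("clustering requires the dihedral stage; enabling it")
    dihedral <- TRUE
  }
  if (cartesian && !superpose) {
    note("Cartesian statistics require superposed structures; ",
         "enabling superposition")
    superpose <- TRUE
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(name) {
    files <<- c(files, name)
    file.path(out_dir, name)
  }
  tsv <- function(df, name) {
    utils::write.table(format_num(df), emit(name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  entries <- if (length(structure_list) == 1L &&
                 file.exists(structure_list))
    parse_structure_list(readLines(structure_list, warn = FALSE))
  else parse_structure_list(structure_list)
  if (!nrow(entries)) stop("structure list stage: empty Structure list")
  selection <- NULL
  if (!is.null(positions)) {
    selection <- if (length(positions) == 1L && file.exists(positions))
      parse_position_list(readLines(positions, warn = FALSE))
    else parse_position_list(positions)
  }

  structures <- withCallingHandlers(
    lapply(seq_len(nrow(entries)), function(i)
      read_pdb(file.path(pdb_dir, paste0(entries$basename[i], ".pdb")),
               chain_spec = entries$chain[i],
               label = entries$basename[i],
               family = if (is.na(entries$family[i])) NULL
               else entries$family[i])),
    warning = function(w) {
      note("read stage: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  families <- if (all(is.na(entries$family))) NULL
  else structure(entries$family, names = entries$basename)

  aln <- if (identical(alignment, "numbering")) align_by_numbering(structures)
  else read_alignment(alignment, structures)
  aln <- renumber(aln, first_position)
  writeLines(paste0(">", aln$labels, "\n",
                    alignment_rows(aln, structures)),
             emit("alignment.fasta"))

  sup <- NULL
  if (superpose) {
    if (is.null(reference)) {
      reference <- structures[[1L]]$label
      note("no reference given; using first structure '", reference, "'")
    }
    sup <- superpose_ensemble(structures, aln, reference = reference,
                              atom_set = atom_set)
    dir.create(file.path(out_dir, "superposed"), showWarnings = FALSE)
    for (s in sup$structures)
      write_pdb(s, emit(file.path("superposed", paste0(s$label, ".pdb"))))
    tsv(data.frame(label = names(sup$rmsd),
                   rmsd_A = sup$rmsd, atoms_used = sup$atoms_used,
                   stringsAsFactors = FALSE), "superposition.tsv")
  }

  if (cartesian)
    tsv(cartesian_table(sup, aln), "cartesian.tsv")

  torsions <- NULL
  if (dihedral) {
    torsions <- ensemble_torsions(structures)
    out_t <- torsions
    out_t$value <- ifelse(is.na(out_t$value), "NA",
                          sprintf("%.4f", out_t$value))
    tsv(out_t[, c("label", "chain", "resno", "icode", "resid", "angle",
                  "value")], "torsions.tsv")
    tsv(position_summaries(torsions, aln, selection = selection,
                           families = families), "circular_summary.tsv")
  }

  clus <- NULL
  if (cluster) {
    dm <- withCallingHandlers(
      dihedral_distance_matrix(torsions, aln, selection = selection,
                               aggregation = aggregation),
      warning = function(w) {
        note("clustering stage: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    dd <- as.data.frame(round(dm$d, 6L))
    tsv(cbind(label = dm$labels, dd), "distances.tsv")
    tree <- linkage_complete(dm)
    write_newick(tree, emit("tree.newick"))
    clus <- cut_tree(tree, radius = radius)
    tsv(data.frame(label = names(clus$labels), cluster = clus$labels,
                   stringsAsFactors = FALSE), "clusters.tsv")
    writeLines(emit_cluster_families(clus, entries),
               emit("cluster_structure_list.txt"))
  }

  summary <- list(
    parameters = list(alignment = if (identical(alignment, "numbering"))
      "numbering" else basename(alignment),
      superpose = superpose, cartesian = cartesian, dihedral = dihedral,
      cluster = cluster, reference = reference, radius = radius,
      first_position = first_position, atom_set = atom_set,
      aggregation = aggregation,
      positions = if (is.null(selection)) "all positions, angles phi psi"
      else paste(c(if (is.null(selection$ranges)) "all positions"
                   else apply(selection$ranges, 1L, function(r)
                     paste0(r[1L], "-", r[2L])),
                   selection$angles), collapse = " ")),
    n_structures = length(structures),
    n_positions = aln$n_columns,
    n_clusters = if (is.null(clus)) NA else length(clus$sizes),
    cluster_sizes = if (is.null(clus)) NULL else clus$sizes,
    outputs = files,
    warnings = warnings)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(summary)
}

# fixed-width numeric formatting so table output is byte-stable
format_num <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.6f", df[[j]])
  }
  df
}
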