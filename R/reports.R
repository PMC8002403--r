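# Batch report generation: the file-producing layer behind the CLI.

#' Read peptide sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (names from the record IDs,
#'   description beyond the first word ignored).
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) err_io(sprintf("FASTA file not found: %s", path))
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    err_dependency("the Biostrings package is required for FASTA input")
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  seqs
}

report_metadata <- function(extra = character(0)) {
  c(sprintf("# peptools %s", as.character(utils::packageVersion("peptools"))),
    "# pKa table: Lehninger side-chain values; termini 9.0 (N), 2.0 (C)",
    "# hydrophobicity: Eisenberg consensus scale (summed)",
    "# logP: Wildman-Crippen atom contributions (Open Babel)",
    "# H-bond convention: donors [#7,#8;!H0], acceptors [#7,#8]",
    extra)
}

write_report_csv <- function(df, path, extra_meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(report_metadata(extra_meta), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Batch sequence report
#'
#' Computes the full property and rule roster for a set of sequences.
#' Records that fail to parse are collected as errors rather than
#' aborting the batch.
#'
#' @param sequences character vector of sequences.
#' @param ids record identifiers (defaults to `seq_1` ...).
#' @param pH pH for the net-charge column.
#' @return A list with `report` (one data-frame row per valid record, the
#'   full descriptor roster) and `errors` (named character vector of
#'   failure messages).
#' @export
sequence_report <- function(sequences, ids = NULL, pH = 7.0) {
  if (is.null(ids)) {
    ids <- if (!is.null(names(sequences))) names(sequences)
           else sprintf("seq_%d", seq_along(sequences))
  }
  rows <- list()
  errors <- character(0)
  for (k in seq_along(sequences)) {
    rec <- tryCatch({
      pr <- suppressWarnings(property_report(sequences[[k]], pH = pH))
      data.frame(id = ids[k], sequence = pr$sequence, length = pr$length,
                 net_charge = pr$net_charge,
                 molecular_weight = pr$molecular_weight,
                 crippen_logp = pr$crippen_logp,
                 hydrophobicity = pr$hydrophobicity_eisenberg,
                 aromaticity = pr$aromaticity,
                 instability_index = pr$instability_index,
                 isoelectric_point = pr$isoelectric_point,
                 n_hbond_donors = pr$n_hbond_donors,
                 n_hbond_acceptors = pr$n_hbond_acceptors,
                 solubility_rules_failed = pr$n_solubility_rules_failed,
                 synthesis_rules_failed = pr$n_synthesis_rules_failed,
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      errors[ids[k]] <- conditionMessage(rec)
    } else {
      rows[[length(rows) + 1L]] <- rec
    }
  }
  list(report = if (length(rows)) do.call(rbind, rows) else NULL,
       errors = errors)
}

#' Run sequence mode
#'
#' The batch entry point behind `peptools.R -m sequence`: computes the
#' descriptor/rule report for a single sequence or a FASTA batch, writes
#' `sequence_report.csv` (with a reproducibility metadata header) and,
#' optionally, one distance-geometry conformer PDB per peptide.
#'
#' @param sequence single sequence (alternative to `fasta`).
#' @param fasta path to a FASTA batch.
#' @param out_dir output directory (created if needed).
#' @param pH pH for net charge.
#' @param conformer also write a conformer PDB per peptide.
#' @param seed seed for conformer generation.
#' @return Invisibly, a list with the report data frame, per-record
#'   errors, and the paths written.
#' @export
run_sequence_mode <- function(sequence = NULL, fasta = NULL, out_dir = ".",
                              pH = 7.0, conformer = FALSE, seed = 1L) {
  if (is.null(sequence) && is.null(fasta)) {
    err_domain("provide a sequence or a FASTA file")
  }
  seqs <- if (!is.null(fasta)) read_fasta_sequences(fasta) else {
    stats::setNames(sequence, "seq_1")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- sequence_report(seqs, pH = pH)
  files <- character(0)
  csv <- file.path(out_dir, "sequence_report.csv")
  if (!is.null(res$report)) {
    write_report_csv(res$report, csv, sprintf("# pH: %g", pH))
    files <- csv
  }
  for (nm in names(res$errors)) {
    message(sprintf("record '%s' skipped: %s", nm, res$errors[[nm]]))
  }
  if (conformer && !is.null(res$report)) {
    for (k in seq_len(nrow(res$report))) {
      conf <- generate_conformer(res$report$sequence[k], seed = seed)
      pdb <- file.path(out_dir, paste0(res$report$id[k], ".pdb"))
      write_pdb(conf, pdb)
      files <- c(files, pdb)
    }
  }
  if (is.null(res$report)) err_domain("all records failed to parse")
  invisible(list(report = res$report, errors = res$errors, files = files))
}

#' Run structure mode
#'
#' The entry point behind `peptools.R -m structure`: loads a protein-peptide
#' complex, counts per-residue non-bonded contacts at the given threshold,
#' annotates secondary structure and relative ASA, writes the per-residue
#' table, the hydrogen-bond graph (GraphML and PNG) and a summary.  If
#' annotation fails (e.g. backbone-free fixtures) contacts are still
#' reported and the structure columns are marked unavailable.
#'
#' @param pdb_path complex PDB file.
#' @param chain peptide chain id.
#' @param threshold contact threshold in Angstrom (default 4.0).
#' @param out_dir output directory.
#' @param cyclic peptide topology flag (graph layout).
#' @return Invisibly, a list with the per-residue table, the hydrogen-bond
#'   graph, the total interface hydrogen-bond count and written paths.
#' @export
run_structure_mode <- function(pdb_path, chain, threshold = 4.0,
                               out_dir = ".", cyclic = FALSE) {
  m <- load_complex(pdb_path, chain)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  contacts <- count_contacts(m, threshold)
  ann <- tryCatch(annotate_structure(m, chain = chain),
                  error = function(e) {
                    warning(sprintf("annotation unavailable: %s",
                                    conditionMessage(e)))
                    NULL
                  })
  tab <- contacts
  if (!is.null(ann)) {
    idx <- match(tab$resno, ann$resno[ann$chain == chain])
    annp <- ann[ann$chain == chain, , drop = FALSE]
    tab$ss <- annp$ss[idx]
    tab$rasa <- annp$rasa[idx]
  } else {
    tab$ss <- NA_character_
    tab$rasa <- NA_real_
  }
  g <- NULL; n_hb <- NA_integer_; files <- character(0)
  if (!is.null(ann)) {
    g <- hydrogen_bond_graph(m, cyclic = cyclic)
    n_hb <- sum(igraph::E(g)$weight)
    gml <- file.path(out_dir, "hbond_graph.graphml")
    png_path <- file.path(out_dir, "hbond_graph.png")
    export_graph(g, gml, "graphml")
    render_graph(g, png_path)
    files <- c(gml, png_path)
  }
  csv <- file.path(out_dir, "structure_report.csv")
  write_report_csv(tab, csv,
                   c(sprintf("# contact threshold: %g A", attr(contacts, "threshold")),
                     sprintf("# interface hydrogen bonds: %s", n_hb)))
  invisible(list(table = tab, graph = g, n_hbonds = n_hb,
                 files = c(csv, files), threshold = attr(contacts, "threshold")))
}
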