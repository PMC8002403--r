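# Protein-peptide complex analysis: parsing, contacts, per-residue
# annotation and the hydrogen-bond interaction graph.

#' Load a protein-peptide complex from PDB
#'
#' Parses a PDB file (first model only for multi-model files), keeps ATOM
#' records (waters/HETATM excluded), keeps alternate location 'A' (or
#' blank), and labels every residue of `peptide_chain` with the peptide
#' role; all other chains are the protein.
#'
#' @param pdb_path path to a PDB file.
#' @param peptide_chain chain identifier of the peptide.
#' @return An object of class `complex_model`: atom table (chain, resno,
#'   resn, elety, element, x, y, z, role) plus `peptide_chain`.
#' @export
load_complex <- function(pdb_path, peptide_chain) {
  if (!file.exists(pdb_path)) err_io(sprintf("PDB file not found: %s", pdb_path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(pdb_path, multi = FALSE, verbose = FALSE)),
    error = function(e) err_empty_structure(paste("cannot parse PDB:",
                                                  conditionMessage(e))))
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (!nrow(a)) err_empty_structure("no ATOM records in structure")
  a <- a[is.na(a$alt) | a$alt %in% c("", "A"), , drop = FALSE]
  if (!(peptide_chain %in% a$chain)) {
    err_chain_not_found(sprintf("chain '%s' not present (chains: %s)",
                                peptide_chain,
                                paste(unique(a$chain), collapse = ", ")))
  }
  element <- a$elesy
  missing_el <- is.na(element) | !nzchar(trimws(element))
  element[missing_el] <- substr(trimws(a$elety[missing_el]), 1, 1)
  atoms <- data.frame(chain = a$chain, resno = a$resno, resn = a$resid,
                      elety = trimws(a$elety), element = trimws(element),
                      x = a$x, y = a$y, z = a$z,
                      role = ifelse(a$chain == peptide_chain, "peptide", "protein"),
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms, peptide_chain = peptide_chain,
                 source = pdb_path),
            class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  ch <- table(x$atoms$chain)
  cat(sprintf("<complex_model> %d atoms, chains: %s (peptide: %s)\n",
              nrow(x$atoms),
              paste(sprintf("%s[%d]", names(ch), ch), collapse = " "),
              x$peptide_chain))
  invisible(x)
}

residue_keys <- function(atoms) {
  u <- unique(atoms[, c("chain", "resno", "resn")])
  u[order(u$chain, u$resno), , drop = FALSE]
}

#' Non-bonded contacts per peptide residue
#'
#' For each residue of the peptide chain, counts the (peptide atom,
#' protein atom) pairs whose Euclidean distance is at most `threshold`
#' (inclusive).  Heavy atoms only by default, since crystal structures
#' usually lack hydrogens.
#'
#' @param m a `complex_model`.
#' @param threshold contact distance threshold in Angstrom (default 4.0).
#' @param include_hydrogens count hydrogen atoms too (default `FALSE`).
#' @return A data frame of class `contact_profile` (resno, resn, contacts)
#'   with the threshold stored in the `"threshold"` attribute.
#' @export
count_contacts <- function(m, threshold = 4.0, include_hydrogens = FALSE) {
  stopifnot(inherits(m, "complex_model"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    err_domain("contact threshold must be a single positive distance")
  }
  a <- m$atoms
  if (!include_hydrogens) a <- a[a$element != "H", , drop = FALSE]
  pep <- a[a$role == "peptide", , drop = FALSE]
  pro <- a[a$role == "protein", , drop = FALSE]
  keys <- residue_keys(pep)
  counts <- integer(nrow(keys))
  if (nrow(pro)) {
    pm <- as.matrix(pro[, c("x", "y", "z")])
    for (k in seq_len(nrow(keys))) {
      ra <- pep[pep$resno == keys$resno[k], c("x", "y", "z"), drop = FALSE]
      d2 <- outer(rowSums(as.matrix(ra)^2), rowSums(pm^2), "+") -
        2 * as.matrix(ra) %*% t(pm)
      counts[k] <- sum(d2 <= threshold^2 + 1e-9)
    }
  }
  structure(data.frame(resno = keys$resno, resn = keys$resn,
                       contacts = counts, stringsAsFactors = FALSE),
            threshold = threshold, class = c("contact_profile", "data.frame"))
}

#' Per-residue structure annotation
#'
#' Assigns a secondary-structure code (DSSP alphabet, via the native
#' Kabsch-Sander implementation) and relative accessible surface area to
#' every residue of the complex.  Raw Shrake-Rupley ASA is normalized by
#' the Tien et al. theoretical maximum per residue type and clamped to
#' `[0, 1]`.
#'
#' @param m a `complex_model`.
#' @param chain optional chain id to restrict the returned table.
#' @return A data frame: chain, resno, resn, ss, asa, rasa.
#' @export
annotate_structure <- function(m, chain = NULL) {
  stopifnot(inherits(m, "complex_model"))
  atoms <- m$atoms
  bb <- backbone_table(atoms)
  n_ok <- sum(!vapply(bb, function(r) anyNA(r$N) || anyNA(r$CA) || anyNA(r$C),
                      logical(1)))
  if (n_ok < 3) {
    err_annotation("backbone atoms needed for at least 3 residues")
  }
  hb <- hbonds_kabsch_sander(m)
  ss <- assign_ss(bb, hb)

  heavy <- atoms[atoms$element != "H", , drop = FALSE]
  asa_atom <- shrake_rupley(as.matrix(heavy[, c("x", "y", "z")]), heavy$element)
  res <- data.frame(chain = vapply(bb, function(r) r$chain, character(1)),
                    resno = vapply(bb, function(r) r$resno, numeric(1)),
                    resn = vapply(bb, function(r) r$resn, character(1)),
                    ss = ss, stringsAsFactors = FALSE)
  res$asa <- vapply(seq_len(nrow(res)), function(k) {
    sum(asa_atom[heavy$chain == res$chain[k] & heavy$resno == res$resno[k]])
  }, numeric(1))
  maxasa <- MAX_ASA[res$resn]
  res$rasa <- pmin(pmax(res$asa / ifelse(is.na(maxasa), 200, maxasa), 0), 1)
  if (!is.null(chain)) res <- res[res$chain == chain, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Hydrogen-bond interaction graph
#'
#' Builds the residue-level hydrogen-bond graph of a complex: nodes are
#' residues (all peptide residues, plus the protein residues engaged in at
#' least one bond), undirected edges are weighted by the number of
#' hydrogen bonds between the residue pair.  By default only bonds
#' crossing the peptide/protein interface are kept; `include_intra` also
#' keeps intra-chain bonds (e.g. helical i,i+4 backbone bonds).  The
#' layout hint is `"spring"` (Fruchterman-Reingold) for cyclic peptides
#' and `"linear"` otherwise.
#'
#' @param m a `complex_model`.
#' @param cyclic logical, peptide topology (controls the layout hint).
#' @param include_intra keep intra-chain hydrogen bonds (default `FALSE`).
#' @param cutoff hydrogen-bond energy cutoff in kcal/mol (default -0.5).
#' @return An `igraph` graph with vertex attributes `role`, `chain`,
#'   `resno`, `label` and edge attribute `weight`; graph attribute
#'   `layout_hint`.
#' @export
hydrogen_bond_graph <- function(m, cyclic = FALSE, include_intra = FALSE,
                                cutoff = KS_DEFAULT_CUTOFF) {
  stopifnot(inherits(m, "complex_model"))
  hb <- hbonds_kabsch_sander(m, cutoff = cutoff)
  pep_chain <- m$peptide_chain
  if (nrow(hb) && !include_intra) {
    crosses <- (hb$donor_chain == pep_chain) != (hb$acceptor_chain == pep_chain)
    hb <- hb[crosses, , drop = FALSE]
  }
  keys <- residue_keys(m$atoms)
  keys$id <- paste0(keys$chain, keys$resno)
  keys$label <- paste0(keys$resn, keys$resno, "(", keys$chain, ")")
  keys$role <- ifelse(keys$chain == pep_chain, "peptide", "protein")

  if (nrow(hb)) {
    e_from <- paste0(hb$donor_chain, hb$donor_resno)
    e_to <- paste0(hb$acceptor_chain, hb$acceptor_resno)
    pair <- t(apply(cbind(e_from, e_to), 1, sort))
    tab <- stats::aggregate(list(weight = rep(1L, nrow(pair))),
                            by = list(a = pair[, 1], b = pair[, 2]), FUN = sum)
  } else {
    tab <- data.frame(a = character(0), b = character(0), weight = integer(0))
  }
  used <- unique(c(tab$a, tab$b))
  nodes <- keys[keys$role == "peptide" | keys$id %in% used, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    tab[, c("a", "b", "weight"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = nodes$id, role = nodes$role,
                          chain = nodes$chain, resno = nodes$resno,
                          label = nodes$label, stringsAsFactors = FALSE))
  g <- igraph::set_graph_attr(g, "layout_hint",
                              if (cyclic) "spring" else "linear")
  g
}

#' Render the interaction graph to an image
#'
#' Draws the hydrogen-bond graph: peptide residues in one fixed colour
#' (yellow), protein residues coloured by chain, edge width linearly
#' proportional to the hydrogen-bond count.  The layout is deterministic
#' for a fixed `layout_seed`.
#'
#' @param g graph from [hydrogen_bond_graph()].
#' @param path output PNG path.
#' @param layout_seed seed for the layout.
#' @param width,height image size in pixels.
#' @return The path, invisibly; node positions and widths are attached as
#'   attributes `"layout"` and `"widths"`.
#' @export
render_graph <- function(g, path, layout_seed = 42L, width = 900,
                         height = 700) {
  role <- igraph::V(g)$role
  chains <- igraph::V(g)$chain
  pro_chains <- unique(chains[role == "protein"])
  palette <- grDevices::hcl.colors(max(1L, length(pro_chains)), "Set 2")
  vcol <- ifelse(role == "peptide", "gold",
                 palette[match(chains, pro_chains)])
  w <- igraph::E(g)$weight
  ew <- if (length(w)) 2 * w else numeric(0)
  set.seed(layout_seed)
  lay <- if (identical(igraph::graph_attr(g, "layout_hint"), "spring")) {
    igraph::layout_with_fr(g)
  } else {
    igraph::layout_with_fr(g)  # spring layout; linear hint orders peptide row
  }
  if (identical(igraph::graph_attr(g, "layout_hint"), "linear")) {
    pep <- which(role == "peptide")
    lay[pep, 1] <- seq_along(pep)
    lay[pep, 2] <- 0
  }
  ok <- tryCatch({
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
    igraph::plot.igraph(g, layout = lay, vertex.color = vcol,
                        vertex.label = igraph::V(g)$label,
                        vertex.size = 18, edge.width = ew,
                        edge.color = "darkorange")
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) err_io(sprintf("cannot render graph to '%s'", path))
  attr(path, "layout") <- lay
  attr(path, "widths") <- ew
  invisible(path)
}

#' Export the interaction graph
#'
#' Writes the hydrogen-bond graph in GraphML or DOT format.
#' @param g graph from [hydrogen_bond_graph()].
#' @param path output path.
#' @param format `"graphml"` or `"dot"`.
#' @return The path, invisibly.
#' @export
export_graph <- function(g, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
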