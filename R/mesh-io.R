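# bin per-element (E, nu) into at most `bins` material groups per distinct
# nu: E takes the centre of its bin, so |E_binned - E| <= range / (2 bins)
bin_materials <- function(materials, bins = 100L) {
  E <- materials$E; nu <- materials$nu
  out_E <- numeric(length(E))
  group <- integer(length(E))
  gi <- 0L
  for (nv in sort(unique(nu))) {
    sel <- nu == nv
    Es <- E[sel]
    rng <- range(Es)
    if (rng[1] == rng[2]) {
      gi <- gi + 1L
      group[sel] <- gi
      out_E[sel] <- Es
      next
    }
    edges <- seq(rng[1], rng[2], length.out = bins + 1L)
    bi <- findInterval(Es, edges, all.inside = TRUE)
    centres <- (edges[-1] + edges[-length(edges)]) / 2
    used <- sort(unique(bi))
    group[sel] <- gi + match(bi, used)
    out_E[sel] <- centres[bi]
    gi <- gi + length(used)
  }
  list(E = out_E, nu = nu, group = group)
}

#' Write a mesh to Abaqus-input or VTK format
#'
#' The Abaqus dialect writes `*NODE`, `*ELEMENT, TYPE=C3D10` blocks per
#' part, `*NSET` records for the node sets, and per-element materials
#' binned into at most `bins` groups per Poisson ratio (`*ELSET` +
#' `*SOLID SECTION` + `*MATERIAL`/`*ELASTIC`); the VTK dialect carries the
#' exact unbinned per-element modulus as a cell field. Both writers are
#' bit-stable given fixed inputs.
#'
#' @param mesh a [tet_mesh()].
#' @param materials per-element material field covering all elements.
#' @param path output file.
#' @param dialect `"abaqus-inp"` or `"vtk"`.
#' @param bins material-group count for the Abaqus dialect (default 100).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, materials, path,
                       dialect = c("abaqus-inp", "vtk"), bins = 100L) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (nrow(materials) != nrow(mesh$elements))
    stop("materials must cover all elements")
  dialect <- match.arg(dialect)
  if (dialect == "vtk")
    return(write_solution_vtk(mesh, path, sol = NULL, materials = materials))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open path for writing: ", path))
  on.exit(close(con))
  writeLines(c("*HEADING", "tmjfem C3D10 export"), con)
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.17g, %.17g, %.17g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  for (pn in names(mesh$part_names)) {
    pid <- mesh$part_names[[pn]]
    sel <- which(mesh$part_id == pid)
    if (!length(sel)) next
    writeLines(sprintf("*ELEMENT, TYPE=C3D10, ELSET=PART_%s", toupper(pn)),
               con)
    e <- mesh$elements[sel, , drop = FALSE]
    writeLines(paste0(sel, ", ", apply(e, 1L, paste, collapse = ", ")), con)
  }
  for (ns in names(mesh$node_sets)) {
    ids <- mesh$node_sets[[ns]]
    if (!length(ids)) next
    writeLines(sprintf("*NSET, NSET=%s", toupper(ns)), con)
    writeLines(vapply(split(ids, ceiling(seq_along(ids) / 10)),
                      paste, character(1), collapse = ", "), con)
  }
  bm <- bin_materials(materials, bins)
  for (g in sort(unique(bm$group))) {
    sel <- which(bm$group == g)
    writeLines(sprintf("*ELSET, ELSET=MAT_%d", g), con)
    writeLines(vapply(split(sel, ceiling(seq_along(sel) / 10)),
                      paste, character(1), collapse = ", "), con)
  }
  for (g in sort(unique(bm$group))) {
    sel <- which(bm$group == g)
    writeLines(c(
      sprintf("*SOLID SECTION, ELSET=MAT_%d, MATERIAL=MAT_%d", g, g),
      sprintf("*MATERIAL, NAME=MAT_%d", g),
      "*ELASTIC",
      sprintf("%.17g, %.17g", bm$E[sel[1]], bm$nu[sel[1]])), con)
  }
  invisible(path)
}

#' Read back an Abaqus input file written by [write_mesh()]
#'
#' Parses the subset emitted by the package's own writer (`*NODE`,
#' `*ELEMENT TYPE=C3D10`, `*NSET`, `*ELSET`, `*SOLID SECTION`,
#' `*ELASTIC`); the round trip reproduces nodes and connectivity exactly.
#'
#' @param path input file.
#' @return A list with `mesh` (a [tet_mesh()]) and `materials` (binned
#'   per-element field).
#' @export
read_inp <- function(path) {
  lines <- readLines(path)
  ikey <- grep("^\\*", lines)
  blocks <- list()
  for (b in seq_along(ikey)) {
    from <- ikey[b] + 1L
    to <- if (b < length(ikey)) ikey[b + 1L] - 1L else length(lines)
    blocks[[b]] <- list(head = lines[ikey[b]],
                        body = if (from <= to) lines[from:to] else character(0))
  }
  nodes <- NULL
  elems <- list(); parts <- list()
  nsets <- list()
  elsets <- list()
  sections <- list()
  cur_mat <- NULL
  for (b in blocks) {
    h <- toupper(b$head)
    if (startsWith(h, "*NODE")) {
      v <- do.call(rbind, lapply(strsplit(b$body, ","), as.numeric))
      nodes <- v[order(v[, 1]), 2:4, drop = FALSE]
    } else if (startsWith(h, "*ELEMENT")) {
      pn <- sub(".*ELSET=PART_", "", h)
      v <- do.call(rbind, lapply(strsplit(b$body, ","), as.integer))
      elems[[length(elems) + 1L]] <- v
      parts[[length(parts) + 1L]] <- tolower(pn)
    } else if (startsWith(h, "*NSET")) {
      nm <- tolower(sub(".*NSET=", "", h))
      nsets[[nm]] <- as.integer(unlist(strsplit(paste(b$body, collapse = ","),
                                                ",")))
    } else if (startsWith(h, "*ELSET")) {
      nm <- sub(".*ELSET=", "", h)
      elsets[[nm]] <- as.integer(unlist(strsplit(paste(b$body,
                                                       collapse = ","), ",")))
    } else if (startsWith(h, "*SOLID SECTION")) {
      es <- sub(".*ELSET=([^,]+).*", "\\1", h)
      mt <- sub(".*MATERIAL=([^,]+).*", "\\1", h)
      sections[[es]] <- mt
    } else if (startsWith(h, "*MATERIAL")) {
      cur_mat <- sub(".*NAME=([^,]+).*", "\\1", h)
    } else if (startsWith(h, "*ELASTIC")) {
      v <- as.numeric(strsplit(b$body[1], ",")[[1]])
      attr(sections, cur_mat) <- v
      sections[[paste0("props_", cur_mat)]] <- v
    }
  }
  all_e <- do.call(rbind, elems)
  ord <- order(all_e[, 1])
  conn <- all_e[ord, 2:11, drop = FALSE]
  part_id <- integer(nrow(conn))
  part_names <- stats::setNames(seq_along(parts), unlist(parts))
  row_of <- match(seq_len(nrow(conn)), all_e[ord, 1])
  k <- 0L
  for (p in seq_along(elems)) {
    ids <- elems[[p]][, 1]
    part_id[ids] <- p
  }
  E <- numeric(nrow(conn)); nu <- numeric(nrow(conn))
  for (es in names(sections)) {
    if (startsWith(es, "props_") || startsWith(es, "MAT_") == FALSE) next
    props <- sections[[paste0("props_", sections[[es]])]]
    ids <- elsets[[es]]
    E[ids] <- props[1]; nu[ids] <- props[2]
  }
  materials <- structure(data.frame(E = E, nu = nu,
                                    provenance = "binned"),
                         class = c("element_material_field", "data.frame"))
  list(mesh = tet_mesh(nodes, conn, part_id, part_names,
                       node_sets = nsets),
       materials = materials)
}
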