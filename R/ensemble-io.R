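# Reading and writing label-pair ensembles: frames TSV dialect and
# multi-model PDB. A canonical in-frame atom template makes the PDB path
# testable without real structures.

#' Default atom-name mapping for label selection in PDB files
#'
#' Selection is by (chain, residue name, atom name). `ring` lists the
#' isoindoline ring heavy atoms (ordering fixes the z-axis sign), `N`/`O`
#' the nitroxide atoms, and `d1` the four atoms defining the d1 dihedral
#' (bond 1-2, pseudo-bond 2-3 across the amine bridge, bond 3-4).
#'
#' @return nested list with entries `A`, `B` (chain + resname per label)
#'   and `atoms` (shared atom names).
#' @export
default_label_map <- function() {
  list(A = list(chain = "A", resname = "GSP"),
       B = list(chain = "B", resname = "GSP"),
       atoms = list(ring = c("C1R", "C2R", "C3R", "C4R", "C5R", "C6R"),
                    N = "N1", O = "O1",
                    d1 = c("N9", "C2A", "C7A", "C1R")))
}

# Canonical label atoms in nitroxide-frame coordinates (Angstrom, plane =
# xy, N-O along +x, spin center at the origin). The purine-side d1 atom N9
# flips across the d1 axis (the x line) between syn and anti.
.label_template <- function(conformer = "syn") {
  ring <- rbind(C1R = c(-1.35,  1.15, 0),
                C2R = c(-2.75,  0.70, 0),
                C3R = c(-2.75, -0.70, 0),
                C4R = c(-1.35, -1.15, 0),
                C5R = c(-4.05, -1.40, 0),
                C6R = c(-4.05,  1.40, 0))
  y9 <- if (identical(conformer, "syn")) 1.0 else -1.0
  list(ring = ring,
       N = c(-0.65, 0, 0), O = c(0.65, 0, 0),
       d1 = rbind(N9  = c(-5.95, y9, 0),
                  C2A = c(-5.25, 0, 0),
                  C7A = c(-3.85, 0, 0),
                  C1R = c(-1.35, 1.15, 0)))
}

#' Synthesize label atoms from a nitroxide frame
#'
#' Places the canonical isoindoline/purine atom template into the
#' laboratory frame of `frame`, with the purine-side dihedral atom
#' reflecting the requested syn/anti state. Inverse of [build_frame] up to
#' template rigidity; used to write synthetic ensembles as multi-model PDB.
#'
#' @param frame a [nitroxide_frame].
#' @param conformer `"syn"` or `"anti"`.
#' @return list with `ring` matrix, `N`, `O`, `d1` in lab coordinates (A).
#' @export
frame_to_atoms <- function(frame, conformer = "syn") {
  tpl <- .label_template(conformer)
  R <- frame_matrix(frame)
  place <- function(p) {
    p <- rbind(p)
    t(R %*% t(p)) + matrix(frame$origin, nrow(p), 3, byrow = TRUE)
  }
  out <- list(ring = place(tpl$ring),
              N = drop(place(tpl$N)), O = drop(place(tpl$O)),
              d1 = place(tpl$d1))
  rownames(out$ring) <- rownames(tpl$ring)
  rownames(out$d1) <- rownames(tpl$d1)
  out
}

.atoms_to_pair <- function(atoms_A, atoms_B) {
  fr_A <- build_frame(atoms_A)
  fr_B <- build_frame(atoms_B)
  conf <- function(a) classify_conformer(dihedral_d1(a$d1[1, ], a$d1[2, ], a$d1[3, ], a$d1[4, ]))
  spin_pair(fr_A, fr_B, conformer = c(conf(atoms_A), conf(atoms_B)))
}

#' Read a label-pair ensemble
#'
#' Dispatches on file extension: `.pdb` for multi-model PDB (models
#' delimited by MODEL/ENDMDL, atoms selected by the `label_map`), anything
#' else for the frames TSV dialect written by [write_ensemble]. Oxygen
#' in-plane projection is applied to every label when building frames from
#' atoms.
#'
#' @param path file path.
#' @param label_map selection mapping, see [default_label_map] (PDB only).
#' @return list of [spin_pair] objects, class `spin_pair_ensemble`, in
#'   model order.
#' @export
read_ensemble <- function(path, label_map = default_label_map()) {
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    .read_ensemble_pdb(path, label_map)
  } else {
    .read_ensemble_tsv(path)
  }
}

.required_atom_names <- function(label_map) {
  unique(c(label_map$atoms$ring, label_map$atoms$N, label_map$atoms$O,
           label_map$atoms$d1))
}

.read_ensemble_pdb <- function(path, label_map) {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) {
    blocks <- list(grep("^(ATOM|HETATM)", lines, value = TRUE))
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records", call. = FALSE)
    blocks <- mapply(function(s, e) grep("^(ATOM|HETATM)", lines[s:e], value = TRUE),
                     model_starts, model_ends, SIMPLIFY = FALSE)
  }
  need <- .required_atom_names(label_map)
  pairs <- vector("list", length(blocks))
  for (m in seq_along(blocks)) {
    rec <- blocks[[m]]
    name <- trimws(substr(rec, 13, 16))
    resname <- trimws(substr(rec, 18, 20))
    chain <- trimws(substr(rec, 22, 22))
    xyz <- cbind(as.numeric(substr(rec, 31, 38)),
                 as.numeric(substr(rec, 39, 46)),
                 as.numeric(substr(rec, 47, 54)))
    if (anyNA(xyz))
      stop(sprintf("model %d: unparseable coordinate record", m), call. = FALSE)
    get_label <- function(side) {
      sel <- label_map[[side]]
      idx <- which(chain == sel$chain & resname == sel$resname)
      pick <- function(nm) {
        i <- idx[match(nm, name[idx])]
        if (anyNA(i))
          stop(sprintf("model %d: label %s is missing atom(s) %s", m, side,
                       paste(nm[is.na(i)], collapse = ", ")), call. = FALSE)
        xyz[i, , drop = FALSE]
      }
      list(ring = pick(label_map$atoms$ring),
           N = drop(pick(label_map$atoms$N)),
           O = drop(pick(label_map$atoms$O)),
           d1 = pick(label_map$atoms$d1))
    }
    pairs[[m]] <- .atoms_to_pair(get_label("A"), get_label("B"))
  }
  structure(pairs, class = "spin_pair_ensemble")
}

#' Write a label-pair ensemble as multi-model PDB
#'
#' Each model contains the two labels rebuilt from their frames with the
#' canonical atom template (synthetic coordinates, chains/resnames from
#' `label_map`). Round-trips through [read_ensemble] at PDB coordinate
#' precision (1e-3 Angstrom).
#'
#' @param ensemble `spin_pair_ensemble`.
#' @param path output path.
#' @param label_map naming scheme, see [default_label_map].
#' @export
write_ensemble_pdb <- function(ensemble, path, label_map = default_label_map()) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(serial, nm, resn, ch, resno, p) {
    el <- substr(nm, 1, 1)
    sprintf("HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, nm, resn, ch, resno, p[1], p[2], p[3], el)
  }
  for (m in seq_along(ensemble)) {
    g <- ensemble[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    for (which in c("A", "B")) {
      fr <- if (which == "A") g$frame_A else g$frame_B
      st <- g$conformer[if (which == "A") 1L else 2L]
      at <- frame_to_atoms(fr, st)
      sel <- label_map[[which]]
      coords <- rbind(at$ring, N1 = at$N, O1 = at$O,
                      at$d1[setdiff(rownames(at$d1), rownames(at$ring)), , drop = FALSE])
      rownames(coords)[rownames(coords) == "N1"] <- label_map$atoms$N
      rownames(coords)[rownames(coords) == "O1"] <- label_map$atoms$O
      for (i in seq_len(nrow(coords))) {
        serial <- serial + 1L
        writeLines(fmt(serial, rownames(coords)[i], sel$resname, sel$chain, 1L,
                       coords[i, ]), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

.tsv_cols <- c("model", "label",
               "origin_x", "origin_y", "origin_z",
               "xax_x", "xax_y", "xax_z",
               "yax_x", "yax_y", "yax_z",
               "zax_x", "zax_y", "zax_z")

#' Write a label-pair ensemble as a frames table (TSV)
#'
#' One row per label per model: columns `model`, `label` (A|B), origin in
#' Angstrom and the three axis unit vectors, all printed with 6 decimals,
#' plus a `conformer` column. Reading the file back reproduces origins and
#' axes at printed precision.
#'
#' @param ensemble `spin_pair_ensemble`.
#' @param path output path.
#' @export
write_ensemble <- function(ensemble, path) {
  rows <- lapply(seq_along(ensemble), function(m) {
    g <- ensemble[[m]]
    one <- function(fr, lab, st) {
      data.frame(model = m, label = lab,
                 origin_x = fr$origin[1], origin_y = fr$origin[2], origin_z = fr$origin[3],
                 xax_x = fr$x[1], xax_y = fr$x[2], xax_z = fr$x[3],
                 yax_x = fr$y[1], yax_y = fr$y[2], yax_z = fr$y[3],
                 zax_x = fr$z[1], zax_y = fr$z[2], zax_z = fr$z[3],
                 conformer = st)
    }
    rbind(one(g$frame_A, "A", g$conformer[1]), one(g$frame_B, "B", g$conformer[2]))
  })
  df <- do.call(rbind, rows)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "model"
  df[num] <- lapply(df[num], function(v) sprintf("%.6f", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_ensemble_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(.tsv_cols, names(df))
  if (length(missing) > 0L)
    stop("frames table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"conformer" %in% names(df)) df$conformer <- "syn"
  models <- sort(unique(df$model))
  pairs <- lapply(models, function(m) {
    sub <- df[df$model == m, ]
    get <- function(lab) {
      row <- sub[sub$label == lab, ]
      if (nrow(row) != 1L)
        stop(sprintf("model %d: expected exactly one row for label %s", m, lab),
             call. = FALSE)
      list(frame = nitroxide_frame(
             origin = c(row$origin_x, row$origin_y, row$origin_z),
             x_axis = c(row$xax_x, row$xax_y, row$xax_z),
             y_axis = c(row$yax_x, row$yax_y, row$yax_z),
             z_axis = c(row$zax_x, row$zax_y, row$zax_z)),
           conformer = row$conformer)
    }
    a <- get("A"); b <- get("B")
    spin_pair(a$frame, b$frame, conformer = c(a$conformer, b$conformer))
  })
  structure(pairs, class = "spin_pair_ensemble")
}

#' @export
print.spin_pair_ensemble <- function(x, ...) {
  r <- vapply(x, function(g) g$r, numeric(1))
  cat(sprintf("Spin-pair ensemble: %d members, r = %.3f +/- %.3f nm\n",
              length(x), mean(r), stats::sd(r)))
  st <- table(vapply(x, function(g) paste(g$conformer, collapse = "-"), character(1)))
  cat("  conformer states:", paste(sprintf("%s %d", names(st), st), collapse = ", "), "\n")
  invisible(x)
}

#' Distances of an ensemble
#' @param ensemble `spin_pair_ensemble`.
#' @return numeric vector of inter-spin distances (nm).
#' @export
ensemble_distances <- function(ensemble) {
  vapply(ensemble, function(g) g$r, numeric(1))
}
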