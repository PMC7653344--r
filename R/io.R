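# Readers and writers. All formats are plain delimited text: tab-separated
# with '#' comment lines (diff-friendly, no quoting ambiguity). Units are
# fixed package-wide (Angstrom, kcal/mol, e) and not configurable.

#' Read a PQR file
#'
#' Whitespace-delimited ATOM/HETATM records carrying per-atom charge and
#' radius (the last two numeric fields). Both the 10-field (no chain) and
#' 11-field (with chain) layouts are accepted. Atom serials are preserved.
#'
#' @param path Path to a PQR file.
#' @return An [atom_spheres()] data frame with additional columns `serial`,
#'   `name`, `resname`, `resseq`; `atom_type` is the PQR atom name.
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) stop_fe("PQR file not found: %s", path)
  lines <- readLines(path)
  sel <- grep("^(ATOM|HETATM)", lines)
  if (!length(sel)) stop_fe("no ATOM/HETATM records in %s", path)
  rec <- lapply(sel, function(ln) {
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (!length(f) %in% c(10L, 11L)) {
      stop_fe("%s line %d: expected 10 or 11 fields, got %d",
              path, ln, length(f))
    }
    has_chain <- length(f) == 11L
    num <- suppressWarnings(as.numeric(f[(length(f) - 4):length(f)]))
    if (anyNA(num)) {
      stop_fe("%s line %d: non-numeric coordinate/charge/radius field",
              path, ln)
    }
    list(serial = suppressWarnings(as.integer(f[2])), name = f[3],
         resname = f[4], resseq = f[if (has_chain) 6 else 5],
         x = num[1], y = num[2], z = num[3], charge = num[4],
         radius = num[5])
  })
  x <- vapply(rec, `[[`, numeric(1), "x")
  out <- atom_spheres(x,
                      vapply(rec, `[[`, numeric(1), "y"),
                      vapply(rec, `[[`, numeric(1), "z"),
                      radius = vapply(rec, `[[`, numeric(1), "radius"),
                      atom_type = vapply(rec, `[[`, character(1), "name"),
                      charge = vapply(rec, `[[`, numeric(1), "charge"))
  out$serial <- vapply(rec, `[[`, integer(1), "serial")
  out$name <- vapply(rec, `[[`, character(1), "name")
  out$resname <- vapply(rec, `[[`, character(1), "resname")
  out$resseq <- vapply(rec, `[[`, character(1), "resseq")
  out
}

#' Write a PQR file
#'
#' @param atoms An [atom_spheres()] object (columns `serial`, `name`,
#'   `resname`, `resseq` are used when present).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(atoms, path) {
  n <- nrow(atoms)
  serial <- atoms$serial %||% seq_len(n)
  name <- atoms$name %||% atoms$atom_type
  resname <- atoms$resname %||% rep("LIG", n)
  resseq <- atoms$resseq %||% rep("1", n)
  charge <- ifelse(is.na(atoms$charge), 0, atoms$charge)
  writeLines(sprintf("ATOM  %5d %-4s %-4s %4s %11.6f %11.6f %11.6f %8.4f %7.4f",
                     serial, name, resname, resseq,
                     atoms$x, atoms$y, atoms$z, charge, atoms$radius),
             path)
  invisible(path)
}

#' Read coordinates from a PDB file, assigning radii by element
#'
#' Standard fixed-column ATOM/HETATM records. PDB files carry no radii;
#' they are assigned from an element lookup table (Bondi-style van der
#' Waals radii by default). The element comes from columns 77-78 when
#' present, otherwise from the first letter of the atom name.
#'
#' @param path Path to a PDB file.
#' @param element_radii Named vector mapping element symbol (upper case) to
#'   radius in Angstrom.
#' @return An [atom_spheres()] data frame; `atom_type` is the element.
#' @export
read_pdb_atoms <- function(path, element_radii = default_element_radii) {
  if (!file.exists(path)) stop_fe("PDB file not found: %s", path)
  lines <- readLines(path)
  sel <- grep("^(ATOM  |HETATM)", lines)
  if (!length(sel)) stop_fe("no ATOM/HETATM records in %s", path)
  fx <- function(ln, a, b) substr(lines[ln], a, b)
  xs <- as.numeric(sapply(sel, fx, 31, 38))
  ys <- as.numeric(sapply(sel, fx, 39, 46))
  zs <- as.numeric(sapply(sel, fx, 47, 54))
  if (anyNA(xs) || anyNA(ys) || anyNA(zs)) {
    bad <- sel[which(is.na(xs) | is.na(ys) | is.na(zs))[1]]
    stop_fe("%s line %d: malformed coordinate field", path, bad)
  }
  elem <- toupper(trimws(sapply(sel, fx, 77, 78)))
  fallback <- !nzchar(elem)
  if (any(fallback)) {
    nm <- trimws(sapply(sel[fallback], fx, 13, 16))
    elem[fallback] <- toupper(substr(gsub("[^A-Za-z].*", "", nm), 1, 1))
  }
  unknown <- setdiff(unique(elem), names(element_radii))
  if (length(unknown)) {
    stop_fe("no radius for element(s): %s (extend 'element_radii')",
            paste(unknown, collapse = ", "))
  }
  atom_spheres(xs, ys, zs, radius = unname(element_radii[elem]),
               atom_type = elem)
}

#' Read an energy-component table
#'
#' Tab-separated with a header and `#` comments; one row per (species,
#' replica, frame). Required columns: `species, replica, time_ns, e_int,
#' e_vdw, e_ele, g_pb` and either `g_sa` or `sasa`. `column_map` renames
#' nonstandard headers, e.g. `c(time_ns = "t")` if the file calls the time
#' column `t`.
#'
#' @param path Path to the table.
#' @param column_map Optional named character vector, standard name ->
#'   column name in the file.
#' @return An [energy_frames()] table.
#' @export
read_energy_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop_fe("energy table not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  for (std in names(column_map)) {
    src <- column_map[[std]]
    if (!src %in% names(df)) stop_fe("mapped column '%s' not in %s", src, path)
    names(df)[names(df) == src] <- std
  }
  energy_frames(df)
}

#' Write an energy-component table
#'
#' @param frames An [energy_frames()] table (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(frames, path) {
  utils::write.table(as.data.frame(frames), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Parse MD-log-style energy lines
#'
#' Extracts numeric columns from log lines beginning with a fixed tag
#' (e.g. `"ENERGY:"`), using a column map from field name to whitespace
#' token position (1-based, counting the tag itself as token 1).
#'
#' @param lines Character vector of log lines.
#' @param column_map Named integer vector, e.g.
#'   `c(time_ns = 2, e_vdw = 3, e_ele = 4)`.
#' @param tag Line prefix selecting energy records.
#' @return Data frame with one column per `column_map` entry.
#' @export
parse_energy_log <- function(lines, column_map, tag = "ENERGY:") {
  sel <- grep(paste0("^", tag), lines)
  out <- lapply(names(column_map), function(nm) {
    idx <- column_map[[nm]]
    vapply(sel, function(ln) {
      f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (idx > length(f)) {
        stop_fe("log line %d has %d fields; column '%s' wants field %d",
                ln, length(f), nm, idx)
      }
      v <- suppressWarnings(as.numeric(f[idx]))
      if (is.na(v)) stop_fe("log line %d: field %d is not numeric", ln, idx)
      v
    }, numeric(1))
  })
  names(out) <- names(column_map)
  as.data.frame(out)
}

#' Read dV/dlambda samples
#'
#' Tab-separated with header `leg, lambda, replica, step, dvdl` and `#`
#' comments. The reader validates grid completeness: within each leg every
#' replica must have samples at every lambda window.
#'
#' @param path Path to the sample file.
#' @return Named list of [ti_leg()] objects, one per leg present.
#' @export
read_dvdl <- function(path) {
  if (!file.exists(path)) stop_fe("dvdl file not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("leg", "lambda", "replica", "dvdl")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_fe("missing dvdl column(s): %s", paste(miss, collapse = ", "))
  }
  out <- lapply(split(df, df$leg), function(sub) {
    lams <- sort(unique(sub$lambda))
    reps <- sort(unique(sub$replica))
    have <- table(factor(sub$lambda, lams), factor(sub$replica, reps)) > 0
    if (!all(have)) {
      stop_fe("incomplete lambda grid in leg '%s': every replica needs samples at every window",
              sub$leg[1])
    }
    as_ti_leg(sub, leg = sub$leg[1])
  })
  out
}

#' Build a TI leg from a long sample table
#'
#' @param df Data frame with columns `lambda, replica, dvdl`.
#' @param leg Leg label (`"aqueous"` or `"bound"`).
#' @return A [ti_leg()].
#' @export
as_ti_leg <- function(df, leg = "aqueous") {
  windows <- lapply(split(df, df$lambda), function(w) {
    lambda_window(w$lambda[1],
                  lapply(split(w$dvdl, w$replica), as.numeric))
  })
  ti_leg(unname(windows), leg = leg)
}

#' Write dV/dlambda samples
#'
#' @param legs Named list of [ti_leg()] objects (names are leg labels), or
#'   a single leg.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dvdl <- function(legs, path) {
  if (inherits(legs, "ti_leg")) {
    legs <- stats::setNames(list(legs), legs$leg)
  }
  rows <- do.call(rbind, lapply(names(legs), function(nm) {
    leg <- legs[[nm]]
    do.call(rbind, lapply(leg$windows, function(w) {
      do.call(rbind, lapply(seq_along(w$replicas), function(k) {
        data.frame(leg = nm, lambda = w$lam, replica = k,
                   step = seq_along(w$replicas[[k]]),
                   dvdl = w$replicas[[k]])
      }))
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an experimental affinity table
#'
#' Tab-separated mirror of a published affinity table: columns `ligand,
#' abbreviation, type, pdb, dg_a2a, err_a2a, dg_a1, err_a1`, with `NA` for
#' missing entries (never imputed).
#'
#' @param path Path to the table.
#' @return Data frame with the columns above.
#' @export
read_affinity_table <- function(path) {
  if (!file.exists(path)) stop_fe("affinity table not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("ligand", "abbreviation", "dg_a2a", "err_a2a", "dg_a1", "err_a1")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_fe("missing affinity column(s): %s", paste(miss, collapse = ", "))
  }
  df
}

#' Read and write ligand structure files
#'
#' A minimal small-molecule table format with `@atoms` and `@bonds`
#' sections (tab- or space-separated; `#` comments). The atom block lists
#' `element charge [x y z]`, one atom per line; the bond block lists
#' `i j [order]` with 1-based atom indices. A header comment
#' `# net_charge = <q>` fixes the net charge.
#'
#' @param path File path.
#' @return `read_ligand()`: a [ligand_graph()].
#' @export
read_ligand <- function(path) {
  if (!file.exists(path)) stop_fe("ligand file not found: %s", path)
  lines <- readLines(path)
  nc <- regmatches(lines, regexec("#\\s*net_charge\\s*=\\s*(-?[0-9.]+)", lines))
  nc <- unlist(lapply(nc, function(g) if (length(g) == 2L) g[2] else NULL))
  net <- if (length(nc)) as.numeric(nc[[1]]) else NULL
  lines <- sub("#.*", "", lines)
  sec <- cumsum(grepl("^@", lines))
  labels <- lines[grepl("^@", lines)]
  body <- function(what) {
    k <- which(trimws(labels) == what)
    if (!length(k)) return(character(0))
    x <- lines[sec == k & !grepl("^@", lines)]
    x[nzchar(trimws(x))]
  }
  at <- body("@atoms")
  if (!length(at)) stop_fe("%s: no @atoms section", path)
  af <- strsplit(trimws(at), "\\s+")
  atoms <- data.frame(
    element = vapply(af, `[[`, character(1), 1),
    charge = as.numeric(vapply(af, `[[`, character(1), 2)),
    stringsAsFactors = FALSE)
  if (all(lengths(af) >= 5L)) {
    atoms$x <- as.numeric(vapply(af, `[[`, character(1), 3))
    atoms$y <- as.numeric(vapply(af, `[[`, character(1), 4))
    atoms$z <- as.numeric(vapply(af, `[[`, character(1), 5))
  }
  bd <- body("@bonds")
  bonds <- if (length(bd)) {
    bf <- strsplit(trimws(bd), "\\s+")
    cbind(as.integer(vapply(bf, `[[`, character(1), 1)),
          as.integer(vapply(bf, `[[`, character(1), 2)),
          vapply(bf, function(f) {
            if (length(f) >= 3L) as.integer(f[3]) else 1L
          }, integer(1)))
  } else matrix(integer(0), ncol = 3)
  ligand_graph(atoms, bonds, net_charge = net)
}

#' @rdname read_ligand
#' @param lig A [ligand_graph()] (for `write_ligand`).
#' @export
write_ligand <- function(lig, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# net_charge = %g", lig$net_charge), con)
  writeLines("@atoms", con)
  if (all(c("x", "y", "z") %in% names(lig$atoms))) {
    writeLines(sprintf("%s\t%.6f\t%.6f\t%.6f\t%.6f", lig$atoms$element,
                       lig$atoms$charge, lig$atoms$x, lig$atoms$y,
                       lig$atoms$z), con)
  } else {
    writeLines(sprintf("%s\t%.6f", lig$atoms$element, lig$atoms$charge), con)
  }
  if (nrow(lig$bonds)) {
    writeLines("@bonds", con)
    writeLines(sprintf("%d\t%d\t%d", lig$bonds[, 1], lig$bonds[, 2],
                       lig$bond_order), con)
  }
  invisible(path)
}

#' Write a hybrid ligand as end-state charge sets plus region masks
#'
#' Tab-separated rows `region, l1_idx, l2_idx, element, charge`: common
#' atoms once with their shared (averaged) charge, then the disappearing
#' and appearing atoms with their conservation-adjusted charges.
#'
#' @param hybrid A `"hybrid_ligand"` from [assign_hybrid_charges()].
#' @param l1,l2 The source [ligand_graph()]s (for element labels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hybrid <- function(hybrid, l1, l2, path) {
  cp <- hybrid$common_pairs
  rows <- rbind(
    data.frame(region = "common", l1_idx = cp[, 1], l2_idx = cp[, 2],
               element = l1$atoms$element[cp[, 1]],
               charge = hybrid$common_charges),
    if (length(hybrid$disappearing)) {
      data.frame(region = "disappearing", l1_idx = hybrid$disappearing,
                 l2_idx = NA_integer_,
                 element = l1$atoms$element[hybrid$disappearing],
                 charge = hybrid$disappearing_charges)
    },
    if (length(hybrid$appearing)) {
      data.frame(region = "appearing", l1_idx = NA_integer_,
                 l2_idx = hybrid$appearing,
                 element = l2$atoms$element[hybrid$appearing],
                 charge = hybrid$appearing_charges)
    })
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
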