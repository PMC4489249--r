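# Reporting: per-site interaction collections serialized to parsable XML,
# flat text and a plain-text visualization command script. All numeric
# values are written at fixed 2-decimal precision (PDB coordinate precision
# bounds the meaningful digits); output is byte-identical across runs on
# the same input and configuration (the timestamp is injectable).

.measurement_unit <- function(name) {
  if (grepl("angle|omega|theta|ang", name)) "deg" else "A"
}

.fmt2 <- function(x) sprintf("%.2f", x)

#' Build an interaction report
#'
#' @param structure_id Structure identifier.
#' @param sites List of per-site results: each a list with `site_id`,
#'   `interactions` (seven-type mapping) and optionally `residues`
#'   (character vector of residue labels present in the site, used for
#'   validation).
#' @param cfg The `threshold_config` that produced the interactions,
#'   echoed into the report.
#' @param created Timestamp string; inject a fixed value for reproducible
#'   output.
#' @return Object of class `interaction_report`.
#' @export
build_report <- function(structure_id, sites, cfg = default_thresholds(),
                         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  out_sites <- lapply(sites, function(st) {
    counts <- interaction_counts(st$interactions)
    if (!is.null(st$residues)) {
      labs <- unlist(lapply(.interaction_types, function(t) {
        vapply(st$interactions[[t]], function(x) x$residue, character(1))
      }))
      bad <- setdiff(labs, st$residues)
      if (length(bad) > 0) {
        stop(
          "interaction residue label(s) not present in site ", st$site_id,
          ": ", paste(bad, collapse = ", ")
        )
      }
    }
    list(site_id = st$site_id, interactions = st$interactions, counts = counts)
  })
  structure(
    list(
      structure_id = structure_id,
      created = created,
      config = cfg,
      sites = out_sites
    ),
    class = "interaction_report"
  )
}

#' @export
print.interaction_report <- function(x, ...) {
  cat("<interaction_report>", x$structure_id, "|", length(x$sites), "site(s)\n")
  for (st in x$sites) {
    nz <- st$counts[st$counts > 0]
    cat(
      " ", st$site_id, ":",
      if (length(nz) == 0) "no interactions" else
        paste(names(nz), nz, sep = "=", collapse = ", "),
      "\n"
    )
  }
  invisible(x)
}

.record_to_xml <- function(parent, x, id) {
  rec <- xml2::xml_add_child(parent, "record", id = as.character(id))
  xml2::xml_add_child(rec, "residue", x$residue)
  xml2::xml_add_child(rec, "protein_atoms", paste(x$prot_serials, collapse = ","))
  xml2::xml_add_child(rec, "ligand_atoms", paste(x$lig_serials, collapse = ","))
  xml2::xml_add_child(
    rec, "water",
    if (is.na(x$water_serial)) "" else as.character(x$water_serial)
  )
  xml2::xml_add_child(
    rec, "donor_side",
    if (is.na(x$donor_side)) "n/a" else x$donor_side
  )
  xml2::xml_add_child(
    rec, "subtype",
    if (is.na(x$subtype)) "" else x$subtype
  )
  xml2::xml_add_child(
    rec, "donor_atom",
    if (is.na(x$donor_serial)) "" else as.character(x$donor_serial)
  )
  xml2::xml_add_child(
    rec, "acceptor_atom",
    if (is.na(x$acceptor_serial)) "" else as.character(x$acceptor_serial)
  )
  for (mn in names(x$measurements)) {
    xml2::xml_add_child(
      rec, "measurement", .fmt2(x$measurements[[mn]]),
      name = mn, unit = .measurement_unit(mn)
    )
  }
  invisible(rec)
}

#' Write an interaction report as XML
#'
#' Schema: `report` with `structure_id`, `created`, `config` (one
#' `threshold` element per key, unit attributes), then `bindingsites` with
#' one `bindingsite` per site. Each site carries a `summary` of per-type
#' counts and an `interactions` element with one child per interaction type
#' holding `record` elements (atom serials, residue labels and all
#' measurements with unit attributes, 2-decimal precision).
#'
#' @param report An `interaction_report`.
#' @param path Optional output file.
#' @return The `xml2` document (invisibly when `path` is given).
#' @export
write_report_xml <- function(report, path = NULL) {
  doc <- xml2::xml_new_root("report")
  xml2::xml_add_child(doc, "structure_id", report$structure_id)
  xml2::xml_add_child(doc, "created", report$created)
  cfgnode <- xml2::xml_add_child(doc, "config")
  for (key in names(report$config)) {
    xml2::xml_add_child(
      cfgnode, "threshold", .fmt2(report$config[[key]]),
      name = key, unit = .measurement_unit(key)
    )
  }
  sitesnode <- xml2::xml_add_child(
    doc, "bindingsites", n = as.character(length(report$sites))
  )
  for (st in report$sites) {
    snode <- xml2::xml_add_child(sitesnode, "bindingsite", id = st$site_id)
    sumnode <- xml2::xml_add_child(snode, "summary")
    for (t in .interaction_types) {
      xml2::xml_add_child(
        sumnode, "count", as.character(st$counts[[t]]), type = t
      )
    }
    inode <- xml2::xml_add_child(snode, "interactions")
    for (t in .interaction_types) {
      tnode <- xml2::xml_add_child(
        inode, t, n = as.character(length(st$interactions[[t]]))
      )
      for (i in seq_along(st$interactions[[t]])) {
        .record_to_xml(tnode, st$interactions[[t]][[i]], i)
      }
    }
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

.chr_or_na <- function(x) {
  if (length(x) == 0 || is.na(x) || x == "") NA_character_ else x
}

.int_or_na <- function(x) {
  if (length(x) == 0 || is.na(x) || x == "") NA_integer_ else as.integer(x)
}

#' Read an interaction report back from XML
#'
#' Inverse of [write_report_xml()] up to the declared 2-decimal precision.
#'
#' @param source Path to an XML report file or an `xml2` document.
#' @return An `interaction_report`.
#' @export
read_report_xml <- function(source) {
  doc <- if (inherits(source, "xml_document")) source else xml2::read_xml(source)
  root <- xml2::xml_root(doc)
  cfgnodes <- xml2::xml_find_all(root, "./config/threshold")
  cfg <- structure(
    as.list(as.numeric(xml2::xml_text(cfgnodes))),
    names = xml2::xml_attr(cfgnodes, "name"),
    class = "threshold_config"
  )
  sites <- lapply(
    xml2::xml_find_all(root, "./bindingsites/bindingsite"),
    function(snode) {
      interactions <- lapply(setNames(nm = .interaction_types), function(t) {
        lapply(
          xml2::xml_find_all(snode, paste0("./interactions/", t, "/record")),
          function(rec) {
            get1 <- function(el) {
              xml2::xml_text(xml2::xml_find_first(rec, paste0("./", el)))
            }
            mnodes <- xml2::xml_find_all(rec, "./measurement")
            ds <- get1("donor_side")
            new_interaction(
              type = t,
              residue = get1("residue"),
              prot_serials = as.integer(
                strsplit(get1("protein_atoms"), ",")[[1]]
              ),
              lig_serials = as.integer(
                strsplit(get1("ligand_atoms"), ",")[[1]]
              ),
              measurements = structure(
                as.list(as.numeric(xml2::xml_text(mnodes))),
                names = xml2::xml_attr(mnodes, "name")
              ),
              donor_side = if (ds == "n/a") NA_character_ else ds,
              subtype = .chr_or_na(get1("subtype")),
              water_serial = .int_or_na(get1("water")),
              donor_serial = .int_or_na(get1("donor_atom")),
              acceptor_serial = .int_or_na(get1("acceptor_atom"))
            )
          }
        )
      })
      list(site_id = xml2::xml_attr(snode, "id"), interactions = interactions)
    }
  )
  build_report(
    structure_id = xml2::xml_text(
      xml2::xml_find_first(root, "./structure_id")
    ),
    sites = sites,
    cfg = cfg,
    created = xml2::xml_text(xml2::xml_find_first(root, "./created"))
  )
}

.text_columns <- list(
  hydrophobic = c("RESIDUE", "PROT_ATOM", "LIG_ATOM", "DIST"),
  hbond = c("RESIDUE", "DONOR_SIDE", "PROT_ATOMS", "LIG_ATOMS",
            "DIST_DA", "DON_ANGLE"),
  waterbridge = c("RESIDUE", "PROT_ATOMS", "LIG_ATOMS", "WATER",
                  "DIST_LW", "DIST_PW", "OMEGA"),
  saltbridge = c("RESIDUE", "PROT_ATOMS", "LIG_ATOMS", "DIST"),
  pistack = c("RESIDUE", "SUBTYPE", "PROT_ATOMS", "LIG_ATOMS",
              "CENTDIST", "ANGLE", "OFFSET"),
  pication = c("RESIDUE", "PROT_ATOMS", "LIG_ATOMS", "DIST", "OFFSET"),
  halogen = c("RESIDUE", "PROT_ATOMS", "LIG_ATOMS", "DIST",
              "DON_ANGLE", "ACC_ANGLE")
)

.text_row <- function(type, x) {
  m <- lapply(x$measurements, .fmt2)
  switch(
    type,
    hydrophobic = c(x$residue, x$prot_serials[1], x$lig_serials[1], m$dist),
    hbond = c(
      x$residue, x$donor_side,
      paste(x$prot_serials, collapse = ","),
      paste(x$lig_serials, collapse = ","),
      m$dist_da, m$don_angle
    ),
    waterbridge = c(
      x$residue,
      paste(x$prot_serials, collapse = ","),
      paste(x$lig_serials, collapse = ","),
      x$water_serial, m$dist_lw, m$dist_pw, m$omega
    ),
    saltbridge = c(
      x$residue,
      paste(x$prot_serials, collapse = ","),
      paste(x$lig_serials, collapse = ","),
      m$dist
    ),
    pistack = c(
      x$residue, x$subtype,
      paste(x$prot_serials, collapse = ","),
      paste(x$lig_serials, collapse = ","),
      m$centdist, m$angle, m$offset
    ),
    pication = c(
      x$residue,
      paste(x$prot_serials, collapse = ","),
      paste(x$lig_serials, collapse = ","),
      m$dist, m$offset
    ),
    halogen = c(
      x$residue,
      paste(x$prot_serials, collapse = ","),
      paste(x$lig_serials, collapse = ","),
      m$dist, m$don_angle, m$acc_angle
    )
  )
}

#' Write an interaction report as flat text
#'
#' Per site: a header line, then one fixed-width table per non-empty
#' interaction type. Rows are machine-splittable on the `|` delimiter and
#' every table keeps a constant column count.
#'
#' @param report An `interaction_report`.
#' @param path Optional output file.
#' @return Character vector of text lines (invisibly when `path` is given).
#' @export
write_report_text <- function(report, path = NULL) {
  lines <- c(
    paste0("# interaction report for ", report$structure_id),
    paste0("# created ", report$created),
    ""
  )
  for (st in report$sites) {
    lines <- c(lines, paste0("=== Binding site ", st$site_id, " ==="))
    total <- sum(st$counts)
    if (total == 0) {
      lines <- c(lines, "no interactions detected", "")
      next
    }
    for (t in .interaction_types) {
      recs <- st$interactions[[t]]
      if (length(recs) == 0) next
      header <- .text_columns[[t]]
      rows <- lapply(recs, function(x) as.character(.text_row(t, x)))
      tab <- do.call(rbind, c(list(header), rows))
      widths <- apply(tab, 2, function(col) max(nchar(col)))
      fmt_row <- function(r) {
        paste(
          vapply(
            seq_along(r),
            function(j) formatC(r[j], width = widths[j], flag = "-"),
            character(1)
          ),
          collapse = " | "
        )
      }
      lines <- c(
        lines,
        paste0("** ", t, " (", length(recs), ") **"),
        vapply(seq_len(nrow(tab)), function(i) fmt_row(tab[i, ]), character(1)),
        ""
      )
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

.vis_colors <- c(
  hydrophobic = "grey50", hbond = "blue", waterbridge = "lightblue",
  saltbridge = "yellow", pistack = "green", pication = "orange",
  halogen = "cyan"
)

#' Write a plain-text visualization command script for one site
#'
#' Emits molecular-viewer commands (PyMOL dialect) that load the input
#' structure, select the participating atoms by serial and draw one dashed
#' distance object per interaction, colored by type and named
#' `type_residue_n` (unique names).
#'
#' @param report An `interaction_report`.
#' @param site_id Site identifier as reported (e.g. `"LG1:L:1"`).
#' @param pdb_path Structure path written into the load command.
#' @param path Optional output file.
#' @return Character vector of script lines (invisibly when `path` given).
#' @export
write_vis_script <- function(report, site_id, pdb_path = "input.pdb",
                             path = NULL) {
  ids <- vapply(report$sites, function(st) st$site_id, character(1))
  k <- match(site_id, ids)
  if (is.na(k)) {
    stop(
      "unknown site_id '", site_id, "'; available sites: ",
      paste(ids, collapse = ", ")
    )
  }
  st <- report$sites[[k]]
  lines <- c(
    paste0("# interaction visualization for site ", site_id),
    paste0("load ", pdb_path),
    "bg_color white",
    "hide everything",
    "show cartoon",
    "show sticks, hetatm"
  )
  counter <- 0
  for (t in .interaction_types) {
    for (x in st$interactions[[t]]) {
      counter <- counter + 1
      obj <- paste0(t, "_", gsub("[^A-Za-z0-9-]", "_", x$residue), "_", counter)
      a1 <- x$prot_serials[1]
      a2 <- if (!is.na(x$water_serial)) x$water_serial else x$lig_serials[1]
      sel <- unique(c(x$prot_serials, x$lig_serials, x$water_serial))
      sel <- sel[!is.na(sel)]
      lines <- c(
        lines,
        paste0(
          "select sel_", obj, ", id ",
          paste(sel, collapse = "+")
        ),
        paste0("distance ", obj, ", id ", a1, ", id ", a2),
        paste0("color ", .vis_colors[[t]], ", ", obj)
      )
    }
  }
  lines <- c(lines, "set dash_gap, 0.3", "zoom")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
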