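# End-to-end pipeline and the batch entry point used by the command-line
# wrapper (inst/exec/ligprof).

#' Profile all protein-ligand interactions in a complex
#'
#' Runs the full four-stage pipeline: parse, hydrogenate, select ligands,
#' extract binding sites, characterize, detect and refine.
#'
#' @param input Path to a PDB file or PDB text.
#' @param model Model number for multi-model files (default 1; only the
#'   selected model is analyzed).
#' @param cfg A `threshold_config` (default [default_thresholds()]).
#' @param blacklist Character vector of excluded ligand codes.
#' @param site_cutoff Binding-site envelope distance in Angstrom.
#' @param identifier Optional structure identifier for reporting.
#' @return Object of class `ligprof_profile`: list with `structure`,
#'   `ligands`, `config` and `sites`; each site entry holds the
#'   `binding_site`, its `site_features`, the raw detector output (`raw`)
#'   and the refined `interactions`.
#' @export
profile_complex <- function(input, model = 1, cfg = default_thresholds(),
                            blacklist = default_blacklist(),
                            site_cutoff = 7.5, identifier = NULL) {
  validate_thresholds(cfg)
  s <- parse_pdb(input, model = model, identifier = identifier)
  s <- hydrogenate(s)
  ligs <- filter_ligands(s, blacklist)
  sites <- extract_binding_sites(s, ligs, cutoff = site_cutoff)
  site_results <- lapply(sites, function(st) {
    f <- characterize_site(st)
    raw <- run_all_detectors(f, cfg)
    list(
      site = st,
      features = f,
      raw = raw,
      interactions = refine_interactions(raw)
    )
  })
  structure(
    list(
      structure = s,
      ligands = ligs,
      config = cfg,
      sites = site_results
    ),
    class = "ligprof_profile"
  )
}

#' @export
print.ligprof_profile <- function(x, ...) {
  cat(
    "<ligprof_profile>", x$structure$identifier, "|",
    length(x$sites), "binding site(s)\n"
  )
  for (st in x$sites) {
    counts <- interaction_counts(st$interactions)
    nz <- counts[counts > 0]
    cat(
      " ", st$site$site_id, ":",
      if (length(nz) == 0) "no interactions" else
        paste(names(nz), nz, sep = "=", collapse = ", "),
      "\n"
    )
  }
  invisible(x)
}

#' Summed per-type interaction counts of a profile
#'
#' @param profile A `ligprof_profile`.
#' @return Named integer vector over the seven interaction types.
#' @export
profile_inventory <- function(profile) {
  counts <- setNames(integer(length(.interaction_types)), .interaction_types)
  for (st in profile$sites) {
    counts <- counts + interaction_counts(st$interactions)
  }
  counts
}

#' Build an interaction report from a profile
#'
#' @param profile A `ligprof_profile`.
#' @param created Timestamp string (injectable for reproducible output).
#' @return An `interaction_report`.
#' @export
report_from_profile <- function(profile,
                                created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  sites <- lapply(profile$sites, function(st) {
    a <- st$site$atoms
    list(
      site_id = st$site$site_id,
      interactions = st$interactions,
      residues = unique(vapply(
        seq_len(nrow(a)),
        function(i) .res_label(a, i),
        character(1)
      ))
    )
  })
  build_report(
    structure_id = profile$structure$identifier,
    sites = sites,
    cfg = profile$config,
    created = created
  )
}

#' Batch interaction profiling with report output
#'
#' Processes each input file independently (one failure does not stop the
#' rest): parse, hydrogenate, select ligands, extract sites, characterize,
#' detect, refine, then write the requested output formats into a
#' per-input subdirectory of `out_dir`. A file without ligands yields a
#' warning and an empty report but still counts as success.
#'
#' @param inputs Character vector of PDB files and/or directories
#'   (directories are expanded to their `*.pdb` files).
#' @param out_dir Output directory (created if missing).
#' @param model Model number.
#' @param formats Subset of `c("xml", "txt", "vis")` (default all).
#' @param blacklist Optional path to a blacklist file.
#' @param config Optional path to a threshold key-value file.
#' @param overrides Named numeric overrides applied on top of the config
#'   (mirrors the command-line `--threshold KEY=VALUE` flags).
#' @param site_cutoff Binding-site envelope distance in Angstrom.
#' @param created Timestamp injected into reports (defaults to now).
#' @param verbose Print a per-site summary line.
#' @return List with `status` (0 on success, 1 if any input failed) and
#'   `results` (per input: output paths or the error message).
#' @export
run_profile <- function(inputs, out_dir, model = 1,
                        formats = c("xml", "txt", "vis"),
                        blacklist = NULL, config = NULL, overrides = NULL,
                        site_cutoff = 7.5,
                        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                        verbose = FALSE) {
  files <- character(0)
  for (inp in inputs) {
    if (dir.exists(inp)) {
      files <- c(files, list.files(inp, pattern = "\\.pdb$", full.names = TRUE))
    } else {
      files <- c(files, inp)
    }
  }
  if (length(files) == 0) stop("no input files")
  cfg <- if (is.null(config)) default_thresholds() else read_thresholds(config)
  cfg <- override_thresholds(cfg, overrides)
  bl <- if (is.null(blacklist)) default_blacklist() else read_blacklist(blacklist)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  results <- list()
  status <- 0L
  for (f in files) {
    stem <- sub("\\.[^.]*$", "", basename(f))
    res <- tryCatch({
      if (!file.exists(f)) stop("unreadable input file: ", f)
      prof <- profile_complex(
        f, model = model, cfg = cfg, blacklist = bl,
        site_cutoff = site_cutoff
      )
      if (length(prof$sites) == 0) {
        warning("no ligands found in ", f, "; writing empty report",
                call. = FALSE)
      }
      rep <- report_from_profile(prof, created = created)
      sub <- file.path(out_dir, stem)
      if (!dir.exists(sub)) dir.create(sub, recursive = TRUE)
      written <- character(0)
      if ("xml" %in% formats) {
        p <- file.path(sub, "report.xml")
        write_report_xml(rep, p)
        written <- c(written, p)
      }
      if ("txt" %in% formats) {
        p <- file.path(sub, "report.txt")
        write_report_text(rep, p)
        written <- c(written, p)
      }
      if ("vis" %in% formats) {
        for (st in rep$sites) {
          p <- file.path(
            sub, paste0("vis_", gsub("[^A-Za-z0-9]", "_", st$site_id), ".pml")
          )
          write_vis_script(rep, st$site_id, pdb_path = f, path = p)
          written <- c(written, p)
        }
      }
      if (verbose) {
        for (st in rep$sites) {
          message(
            stem, " ", st$site_id, ": ",
            paste(names(st$counts), st$counts, sep = "=", collapse = " ")
          )
        }
      }
      list(ok = TRUE, files = written, report = rep)
    }, error = function(e) {
      status <<- 1L
      list(ok = FALSE, error = conditionMessage(e))
    })
    results[[stem]] <- res
  }
  list(status = status, results = results)
}
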