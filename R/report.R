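## Multi-condition comparison report: orchestrates volumes, waters,
## displacement, Ringer CC, rotamers and the torsion embedding.

#' Run the full comparative-crystallography pipeline
#'
#' Compares one or more structures against a named reference: cell and
#' protein volumes with percent changes, symmetry-aware unique-water
#' counts, C-alpha displacement summaries, Ringer CC flags when maps are
#' supplied, rotamer-change counts, and (with three or more structures)
#' a torsion-angle PCA embedding. Every number in the report is taken
#' from the stage outputs it aggregates.
#'
#' @param structures Named list of [crystal_structure()] objects; names
#'   are the condition labels.
#' @param reference Name of the reference structure (default: first).
#' @param maps Optional named list of [density_map()] objects matching
#'   `structures` names; enables the Ringer stage.
#' @param thresholds List of analysis thresholds: `water_A` (2.0),
#'   `cc` (0.5), `displacement_A` (0.3), `exclude_ranges` (e.g.
#'   `"375-383"`).
#' @param water_frame Frame-reconciliation mode for [unique_waters()].
#' @param displacement_mode Mode for [ca_distance_profile()].
#' @param compute_protein_volume Grid protein volumes are the slowest
#'   stage; set FALSE to skip.
#' @param grid,probe Parameters for [protein_volume()].
#' @return Object of class `comparison_report` (nested list of stage
#'   outputs plus a `summary` data.frame).
#' @export
run_pipeline <- function(structures, reference = names(structures)[1],
                         maps = NULL,
                         thresholds = list(water_A = 2.0, cc = 0.5,
                                           displacement_A = 0.3,
                                           exclude_ranges = NULL),
                         water_frame = "fractional",
                         displacement_mode = "superposed",
                         compute_protein_volume = TRUE,
                         grid = 0.3, probe = 1.4) {
  if (length(structures) < 2) stop("need at least 2 structures")
  if (is.null(names(structures)) || any(names(structures) == ""))
    names(structures) <- vapply(structures, `[[`, "", "label")
  stopifnot(reference %in% names(structures))
  thr <- utils::modifyList(list(water_A = 2.0, cc = 0.5,
                                displacement_A = 0.3, exclude_ranges = NULL),
                           thresholds)
  ref <- structures[[reference]]
  others <- names(structures)[names(structures) != reference]

  vols <- lapply(structures, function(s) {
    cv <- cell_volume(s$cell)
    pv <- if (compute_protein_volume)
      as.numeric(protein_volume(s, grid = grid, probe = probe)) else NA_real_
    c(cell = cv, protein = pv)
  })
  vol_tab <- data.frame(
    label = names(vols),
    cell_volume_A3 = vapply(vols, `[[`, 0, "cell"),
    protein_volume_A3 = vapply(vols, `[[`, 0, "protein"),
    row.names = NULL, stringsAsFactors = FALSE)
  vol_tab$cell_pct_change <- percent_change(
    vol_tab$cell_volume_A3[vol_tab$label == reference], vol_tab$cell_volume_A3)
  vol_tab$protein_pct_change <- if (compute_protein_volume) percent_change(
    vol_tab$protein_volume_A3[vol_tab$label == reference],
    vol_tab$protein_volume_A3) else NA_real_

  waters <- lapply(others, function(nm) {
    q <- structures[[nm]]
    if (!nrow(water_atoms(q)) || !nrow(water_atoms(ref))) return(NULL)
    unique_waters(q, ref, threshold = thr$water_A, frame = water_frame)
  })
  names(waters) <- others

  displacement <- lapply(others, function(nm) {
    prof <- ca_distance_profile(structures[[nm]], ref,
                                mode = displacement_mode)
    list(profile = prof,
         n_over = sum(prof$ca_dist_A > thr$displacement_A),
         n_total = nrow(prof))
  })
  names(displacement) <- others

  ringer <- NULL
  if (!is.null(maps)) {
    curves <- lapply(names(structures), function(nm) {
      if (is.null(maps[[nm]])) return(NULL)
      ringer_curves(maps[[nm]],
                    strip_to_single_conformer(structures[[nm]]))
    })
    names(curves) <- names(structures)
    ringer <- lapply(others, function(nm) {
      if (is.null(curves[[nm]]) || is.null(curves[[reference]])) return(NULL)
      flag_changed_residues(curves[[reference]], curves[[nm]],
                            threshold = thr$cc,
                            exclude = thr$exclude_ranges)
    })
    names(ringer) <- others
  }

  rotamers <- lapply(others, function(nm)
    rotamer_diff(structures[[nm]], ref, exclude = thr$exclude_ranges))
  names(rotamers) <- others

  embedding <- if (length(structures) >= 3)
    embed_torsions(lapply(names(structures), function(nm) {
      tv <- extract_torsions(structures[[nm]])
      attr(tv, "label") <- nm          # report under the condition name
      tv
    })) else NULL

  summary_tab <- data.frame(
    label = others,
    cell_pct_change = vol_tab$cell_pct_change[match(others, vol_tab$label)],
    unique_waters = vapply(others, function(nm)
      if (is.null(waters[[nm]])) NA_integer_
      else unname(waters[[nm]]$counts["unique"]), integer(1)),
    residues_displaced = vapply(others, function(nm)
      displacement[[nm]]$n_over, integer(1)),
    cc_flagged = vapply(others, function(nm)
      if (is.null(ringer) || is.null(ringer[[nm]])) NA_integer_
      else ringer[[nm]]$count, integer(1)),
    rotamer_changes = vapply(others, function(nm)
      rotamers[[nm]]$count, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(reference = reference, thresholds = thr,
                 volumes = vol_tab, waters = waters,
                 displacement = displacement, ringer = ringer,
                 rotamers = rotamers, embedding = embedding,
                 summary = summary_tab),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Comparison report (reference:", x$reference, ")\n\nVolumes:\n")
  print(transform(x$volumes,
                  cell_volume_A3 = signif(cell_volume_A3, 7),
                  protein_volume_A3 = signif(protein_volume_A3, 6)))
  cat("\nPer-structure summary vs", x$reference, ":\n")
  print(x$summary)
  if (!is.null(x$embedding)) {
    cat("\n")
    print(x$embedding)
  }
  invisible(x)
}

#' Write a comparison report to CSV and JSON
#'
#' Writes `<prefix>_volumes.csv`, `<prefix>_summary.csv` and
#' `<prefix>_report.json` (and per-stage CSVs when present). Floating
#' point values are fixed to 6 significant digits so identical runs give
#' byte-identical files.
#'
#' @param report A `comparison_report` from [run_pipeline()].
#' @param prefix Output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, prefix) {
  sig <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    df
  }
  files <- character()
  w <- function(df, suffix) {
    f <- paste0(prefix, suffix)
    utils::write.csv(sig(df), f, row.names = FALSE)
    files <<- c(files, f)
  }
  w(report$volumes, "_volumes.csv")
  w(report$summary, "_summary.csv")
  for (nm in names(report$displacement))
    w(as.data.frame(report$displacement[[nm]]$profile),
      paste0("_displacement_", nm, ".csv"))
  for (nm in names(report$waters))
    if (!is.null(report$waters[[nm]]))
      w(report$waters[[nm]]$table, paste0("_waters_", nm, ".csv"))
  json <- paste0(prefix, "_report.json")
  jsonlite::write_json(list(
    reference = report$reference,
    thresholds = report$thresholds,
    volumes = sig(report$volumes),
    summary = sig(report$summary)), json, auto_unbox = TRUE, digits = NA,
    null = "null")
  files <- c(files, json)
  invisible(files)
}
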