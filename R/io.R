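## Model and map input/output.
## PDB atom records are read through bio3d; the CRYST1 header (cell +
## space group), which bio3d discards, is parsed from the raw lines.

.water_resids <- c("HOH", "WAT", "DOD")

#' Read a crystal structure from PDB or mmCIF
#'
#' @param path File path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by file extension).
#' @param label Structure label; defaults to the file base name.
#' @return A [crystal_structure()]. Parsing problems that do not prevent
#'   loading (e.g. altloc occupancy sums above 1) are recorded in the
#'   structure's `warnings` field.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  if (format == "pdb") read_structure_pdb(path, label) else read_structure_mmcif(path, label)
}

read_structure_pdb <- function(path, label) {
  lines <- readLines(path, warn = FALSE)
  cryst <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cryst))
    stop("no CRYST1 record in ", path,
         ": a unit cell is required for symmetry-aware stages")
  cell <- unit_cell(as.numeric(substr(cryst[1], 7, 15)),
                    as.numeric(substr(cryst[1], 16, 24)),
                    as.numeric(substr(cryst[1], 25, 33)),
                    as.numeric(substr(cryst[1], 34, 40)),
                    as.numeric(substr(cryst[1], 41, 47)),
                    as.numeric(substr(cryst[1], 48, 54)))
  sg <- trimws(substr(cryst[1], 56, 66))
  if (sg == "") sg <- "P 1"
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, rm.insert = FALSE,
                    verbose = FALSE),
    error = function(e) stop("PDB parse error in ", path, ": ", conditionMessage(e)))
  a <- pdb$atom
  blank_na <- function(v) { v <- as.character(v); v[is.na(v)] <- ""; v }
  resid <- toupper(trimws(a$resid))
  kind <- ifelse(a$type == "ATOM", "polymer",
                 ifelse(resid %in% .water_resids, "water", "het"))
  atoms <- data.frame(element = blank_na(a$elesy),
                      name = trimws(a$elety),
                      altloc = blank_na(a$alt),
                      occ = ifelse(is.na(a$o), 1, a$o),
                      b = ifelse(is.na(a$b), 0, a$b),
                      x = a$x, y = a$y, z = a$z,
                      chain = blank_na(a$chain),
                      resno = as.integer(a$resno),
                      icode = blank_na(a$insert),
                      resid = resid,
                      kind = kind,
                      stringsAsFactors = FALSE)
  crystal_structure(atoms, cell, sg, label)
}

## minimal mmCIF reader for the atom_site loop, cell and space group
read_structure_mmcif <- function(path, label) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(tag) {
    ln <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
    if (!length(ln)) return(NA_character_)
    val <- trimws(sub(paste0("^", tag, "\\s+"), "", ln[1]))
    gsub("^['\"]|['\"]$", "", val)
  }
  cell <- unit_cell(as.numeric(grab("_cell.length_a")),
                    as.numeric(grab("_cell.length_b")),
                    as.numeric(grab("_cell.length_c")),
                    as.numeric(grab("_cell.angle_alpha")),
                    as.numeric(grab("_cell.angle_beta")),
                    as.numeric(grab("_cell.angle_gamma")))
  sg <- grab("_symmetry.space_group_name_H-M")
  if (is.na(sg)) sg <- grab("_space_group.name_H-M_alt")
  if (is.na(sg)) stop("no space group in ", path)

  # locate the atom_site loop
  loop_starts <- grep("^loop_", lines)
  atom_loop <- NULL
  for (s in loop_starts) {
    i <- s + 1
    tags <- character()
    while (i <= length(lines) && grepl("^_", trimws(lines[i]))) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1
    }
    if (any(grepl("^_atom_site\\.", tags))) { atom_loop <- list(tags = tags, body = i); break }
  }
  if (is.null(atom_loop)) stop("no _atom_site loop in ", path)
  tags <- sub("\\s.*$", "", atom_loop$tags)
  i <- atom_loop$body
  rows <- list()
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "loop_") ||
        startsWith(ln, "_")) break
    rows[[length(rows) + 1]] <- scan(text = lines[i], what = character(),
                                     quiet = TRUE, quote = "'\"")
    i <- i + 1
  }
  m <- do.call(rbind, rows)
  if (ncol(m) != length(tags))
    stop("mmCIF atom_site parse error in ", path, ": token/tag count mismatch")
  colnames(m) <- tags
  col <- function(tag, alt = NULL) {
    if (tag %in% tags) return(m[, tag])
    if (!is.null(alt) && alt %in% tags) return(m[, alt])
    rep(NA_character_, nrow(m))
  }
  dot_blank <- function(v) { v[v %in% c(".", "?") | is.na(v)] <- ""; v }
  resid <- toupper(col("_atom_site.auth_comp_id", "_atom_site.label_comp_id"))
  group <- col("_atom_site.group_PDB")
  kind <- ifelse(group == "ATOM", "polymer",
                 ifelse(resid %in% .water_resids, "water", "het"))
  occ <- suppressWarnings(as.numeric(col("_atom_site.occupancy")))
  b <- suppressWarnings(as.numeric(col("_atom_site.B_iso_or_equiv")))
  atoms <- data.frame(element = dot_blank(col("_atom_site.type_symbol")),
                      name = dot_blank(col("_atom_site.auth_atom_id",
                                           "_atom_site.label_atom_id")),
                      altloc = dot_blank(col("_atom_site.label_alt_id")),
                      occ = ifelse(is.na(occ), 1, occ),
                      b = ifelse(is.na(b), 0, b),
                      x = as.numeric(col("_atom_site.Cartn_x")),
                      y = as.numeric(col("_atom_site.Cartn_y")),
                      z = as.numeric(col("_atom_site.Cartn_z")),
                      chain = dot_blank(col("_atom_site.auth_asym_id",
                                            "_atom_site.label_asym_id")),
                      resno = as.integer(col("_atom_site.auth_seq_id",
                                             "_atom_site.label_seq_id")),
                      icode = dot_blank(col("_atom_site.pdbx_PDB_ins_code")),
                      resid = resid,
                      kind = kind,
                      stringsAsFactors = FALSE)
  crystal_structure(atoms, cell, sg, label)
}

#' Write a crystal structure to a PDB file
#'
#' Emits CRYST1, SCALE and ATOM/HETATM records in fixed-column format.
#'
#' @param structure A [crystal_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  cell <- structure$cell
  lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                   cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma,
                   structure$spacegroup, length(structure$ops))
  fm <- frac_matrix(cell)
  for (i in 1:3)
    lines <- c(lines, sprintf("SCALE%d    %10.6f%10.6f%10.6f     %10.5f",
                              i, fm[i, 1], fm[i, 2], fm[i, 3], 0))
  at <- structure$atoms
  for (i in seq_len(nrow(at))) {
    rec <- if (at$kind[i] == "polymer") "ATOM  " else "HETATM"
    nm <- at$name[i]
    # PDB name column convention: element right-justified in cols 13-14
    nm_fmt <- if (nchar(nm) < 4 && nchar(at$element[i]) == 1)
      sprintf(" %-3s", nm) else sprintf("%-4s", nm)
    lines <- c(lines, sprintf(
      "%s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, i %% 100000, nm_fmt, at$altloc[i], at$resid[i], at$chain[i],
      at$resno[i], at$icode[i], at$x[i], at$y[i], at$z[i],
      at$occ[i], at$b[i], at$element[i]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a CCP4/MRC electron-density map
#'
#' Reads mode-2 (32-bit float) maps, honoring the header axis order
#' (MAPC/MAPR/MAPS) and start offsets; the grid is normalized to X,Y,Z
#' axis order with origin at the cell origin. The map must cover exactly
#' one full unit cell.
#'
#' @param path File path.
#' @return A [density_map()].
#' @export
read_ccp4_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, integer(), n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, numeric(), n = 256, size = 4, endian = "little")
  nc <- hdr_int[1]; nr <- hdr_int[2]; ns <- hdr_int[3]
  mode <- hdr_int[4]
  if (mode != 2) stop("only mode-2 (float) CCP4 maps are supported; got mode ", mode)
  starts <- hdr_int[5:7]
  intervals <- hdr_int[8:10]
  cell <- unit_cell(hdr_num[11], hdr_num[12], hdr_num[13],
                    hdr_num[14], hdr_num[15], hdr_num[16])
  axes <- hdr_int[17:19]           # 1=X, 2=Y, 3=Z for columns, rows, sections
  nsymbt <- hdr_int[24]
  seek(con, 1024 + nsymbt)
  vals <- readBin(con, numeric(), n = nc * nr * ns, size = 4, endian = "little")
  arr <- array(vals, dim = c(nc, nr, ns))   # column index fastest
  perm <- order(axes)                        # put X,Y,Z in order
  arr <- aperm(arr, perm)
  dims_xyz <- c(nc, nr, ns)[perm]
  starts_xyz <- starts[perm]
  intervals_xyz <- intervals[c(which(axes == 1), which(axes == 2), which(axes == 3))]
  if (!all(dims_xyz == intervals_xyz))
    stop("map does not cover exactly one unit cell (extent ",
         paste(dims_xyz, collapse = "x"), " vs sampling ",
         paste(intervals_xyz, collapse = "x"), ")")
  # roll so that index 1 corresponds to fractional coordinate 0
  for (ax in 1:3) {
    s <- starts_xyz[ax] %% dims_xyz[ax]
    if (s != 0) {
      idx <- c((dims_xyz[ax] - s + 1):dims_xyz[ax], 1:(dims_xyz[ax] - s))
      arr <- switch(ax, arr[idx, , , drop = FALSE],
                    arr[, idx, , drop = FALSE], arr[, , idx, drop = FALSE])
    }
  }
  density_map(arr, cell)
}

#' Write a density map as a CCP4/MRC file
#'
#' Writes a canonical full-cell, mode-2 map in X,Y,Z axis order with zero
#' start offsets.
#'
#' @param map A [density_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ccp4_map <- function(map, path) {
  dims <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dims); wi(2); wi(c(0, 0, 0)); wi(dims)
  wf(c(map$cell$a, map$cell$b, map$cell$c,
       map$cell$alpha, map$cell$beta, map$cell$gamma))
  wi(c(1, 2, 3))
  wf(c(min(map$values), max(map$values), map$mean))
  wi(1)        # ISPG (space group number; informational)
  wi(0)        # NSYMBT
  wi(rep(0L, 28))            # words 25..52 zero
  writeChar("MAP ", con, 4, eos = NULL)
  wi(0x00004144)             # little-endian machine stamp
  wf(map$rms)
  wi(0)                      # NLABL
  writeBin(raw(800), con)    # label block
  wf(aperm(map$values, c(1, 2, 3)))
  invisible(path)
}
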