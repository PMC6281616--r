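#' Write a system snapshot as extended XYZ
#'
#' One row per site: class token, coordinates, species, leaflet and
#' lipid id.  The comment line carries the box and column layout in the
#' extended-XYZ `Lattice`/`Properties` convention, so external viewers
#' (OVITO, VMD with xyz plugins) can read it.
#'
#' @param system a `cg_system`.
#' @param path output file.
#' @param pos optional positions to write instead of `system$pos` (e.g.
#'   a trajectory snapshot).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(system, path, pos = NULL) {
  if (is.null(pos)) pos <- system$pos
  n <- nrow(pos)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(n), con)
  writeLines(sprintf(
    paste0('Lattice="%g 0 0 0 %g 0 0 0 %g" ',
           'Properties=species:S:1:pos:R:3:species_name:S:1:leaflet:S:1:',
           'lipid:I:1'),
    system$box[1], system$box[2], system$box[3]), con)
  tok <- c(head = "H", body = "B", tail = "T", protein = "P")
  lines <- sprintf("%s %.5f %.5f %.5f %s %s %d",
                   tok[system$class], pos[, 1], pos[, 2], pos[, 3],
                   ifelse(is.na(system$species), "-", system$species),
                   ifelse(is.na(system$leaflet), "-", system$leaflet),
                   ifelse(is.na(system$lipid_id), -1L, system$lipid_id))
  writeLines(lines, con)
  invisible(path)
}

#' Read an extended XYZ snapshot written by [write_xyz()]
#'
#' @param path file path.
#' @return A list with `pos`, `class`, `species`, `leaflet`, `lipid_id`,
#'   and `box`.
#' @export
read_xyz <- function(path) {
  ln <- readLines(path)
  n <- as.integer(ln[1])
  lat <- regmatches(ln[2], regexpr('Lattice="[^"]*"', ln[2]))
  box <- as.numeric(strsplit(sub('Lattice="', "", sub('"$', "", lat)),
                             " ")[[1]])[c(1, 5, 9)]
  f <- strsplit(ln[3:(2 + n)], " +")
  tok <- c(H = "head", B = "body", T = "tail", P = "protein")
  pos <- t(vapply(f, function(v) as.numeric(v[2:4]), numeric(3)))
  list(pos = pos,
       class = unname(tok[vapply(f, `[`, "", 1)]),
       species = ifelse(vapply(f, `[`, "", 5) == "-", NA,
                        vapply(f, `[`, "", 5)),
       leaflet = ifelse(vapply(f, `[`, "", 6) == "-", NA,
                        vapply(f, `[`, "", 6)),
       lipid_id = ifelse(vapply(f, `[`, "", 7) == "-1", NA,
                         as.integer(vapply(f, `[`, "", 7))),
       box = box)
}

#' Export a trajectory as LAMMPS-dump-style text
#'
#' Plain-text frames (`ITEM:`-sectioned) for external visualisation.
#'
#' @param traj a `cg_trajectory`.
#' @param path output file.
#' @param every write every k-th snapshot.
#' @return `path`, invisibly.
#' @export
write_dump <- function(traj, path, every = 1) {
  sys <- traj$system
  con <- file(path, "w")
  on.exit(close(con))
  type_id <- .engine_type_id(sys) + 1L
  ks <- seq(1, length(traj$snapshots), by = every)
  for (k in ks) {
    sn <- traj$snapshots[[k]]
    writeLines(c("ITEM: TIMESTEP", format(traj$times[k], scientific = FALSE),
                 "ITEM: NUMBER OF ATOMS", as.character(nrow(sn)),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("0 %g", sys$box[1]),
                 sprintf("0 %g", sys$box[2]),
                 sprintf("0 %g", sys$box[3]),
                 "ITEM: ATOMS id type x y z"), con)
    writeLines(sprintf("%d %d %.5f %.5f %.5f", seq_len(nrow(sn)),
                       type_id, sn[, 1], sn[, 2], sn[, 3]), con)
  }
  invisible(path)
}
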