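# Plain-text scene serialization: one directory of CSV files (matrices as
# pixels x time tables) plus the ground-truth tables, so scenes can be
# archived and exchanged without binary formats.

.scene_matrices <- c("ndvi", "qa", "fc", "gpp")

#' Write a scene to a directory of CSV files
#'
#' Each pixels x time matrix becomes one CSV; static per-pixel fields go
#' to `pixels.csv`, calendars to `calendar.csv` / `clim_calendar.csv`,
#' and the ground truth to `truth_phi.csv` and `truth_ad.csv`.
#'
#' @param scene A `forest_scene`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "forest_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) {
    utils::write.csv(as.data.frame(x), file.path(dir, name),
                     row.names = FALSE)
  }
  for (nm in .scene_matrices) wcsv(scene[[nm]], paste0(nm, ".csv"))
  for (drv in names(scene$climate))
    wcsv(scene$climate[[drv]], paste0("climate_", drv, ".csv"))
  wcsv(scene$calendar, "calendar.csv")
  wcsv(scene$clim_calendar, "clim_calendar.csv")
  wcsv(data.frame(region = as.character(scene$region),
                  intact = scene$intact, lat = scene$lat,
                  lon = scene$lon), "pixels.csv")
  wcsv(scene$season_mask * 1L, "season_mask.csv")
  wcsv(scene$truth$phi, "truth_phi.csv")
  wcsv(scene$truth$ad, "truth_ad.csv")
  writeLines(c(paste(scene$grid_dim, collapse = ","),
               paste(scene$years, collapse = ",")),
             file.path(dir, "meta.txt"))
  invisible(dir)
}

#' Read a scene written by [write_scene()]
#'
#' @param dir Directory containing the CSV files.
#' @return A `forest_scene` (without the originating `config`).
#' @export
read_scene <- function(dir) {
  rcsv <- function(name) {
    as.matrix(utils::read.csv(file.path(dir, name)))
  }
  meta <- readLines(file.path(dir, "meta.txt"))
  grid_dim <- as.integer(strsplit(meta[1L], ",")[[1L]])
  years <- as.integer(strsplit(meta[2L], ",")[[1L]])
  px <- utils::read.csv(file.path(dir, "pixels.csv"))
  climate <- lapply(c(precip = "precip", temp = "temp", etdef = "etdef",
                      rad = "rad"),
                    function(d) unname(rcsv(paste0("climate_", d, ".csv"))))
  out <- list(
    ndvi = unname(rcsv("ndvi.csv")),
    qa = unname(rcsv("qa.csv")),
    calendar = utils::read.csv(file.path(dir, "calendar.csv")),
    climate = climate,
    clim_calendar = utils::read.csv(file.path(dir, "clim_calendar.csv")),
    fc = unname(rcsv("fc.csv")),
    gpp = unname(rcsv("gpp.csv")),
    years = years,
    region = factor(px$region,
                    levels = unique(px$region[order(px$lat,
                                                    decreasing = TRUE)])),
    intact = px$intact,
    season_mask = unname(rcsv("season_mask.csv")) > 0,
    lat = px$lat, lon = px$lon, grid_dim = grid_dim,
    truth = list(phi = unname(rcsv("truth_phi.csv")),
                 ad = utils::read.csv(file.path(dir, "truth_ad.csv"))),
    config = NULL
  )
  storage.mode(out$qa) <- "integer"
  structure(out, class = "forest_scene")
}
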