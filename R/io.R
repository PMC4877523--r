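#' Import / export plant tables
#'
#' Plant tables are exchanged as plain CSV with header `x,y,biomass,age`.
#' On import, ids are assigned sequentially and `Bmax` is initialized to
#' the imported biomass.
#'
#' @param path CSV file path.
#' @param pop A [new_population()] table.
#' @return `read_plants()` returns a population; `write_plants()` returns
#'   `path` invisibly.
#' @export
read_plants <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "biomass", "age")
  if (!all(need %in% names(df)))
    stop("plant CSV must have columns x,y,biomass,age")
  new_population(id = seq_len(nrow(df)), x = df$x, y = df$y,
                 age = df$age, B = df$biomass, Bmax = df$biomass)
}

#' @rdname read_plants
#' @export
write_plants <- function(pop, path) {
  utils::write.csv(data.frame(x = pop$x, y = pop$y, biomass = pop$B,
                              age = pop$age),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a simulation's outputs as CSV files
#'
#' Writes `summary.csv` (the output time series), one plant table per
#' snapshot (`plants_t<days>.csv` with columns
#' `t,id,x,y,age,biomass,bmax`), and one plain CSV matrix per water field
#' per snapshot (`O_t<days>.csv`, `W_t<days>.csv`).
#'
#' @param out A [run_simulation()] `sim_output`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(out, dir) {
  stopifnot(inherits(out, "sim_output"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$series, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  for (sn in out$snapshots) {
    tag <- format(sn$time, trim = TRUE)
    p <- sn$plants
    utils::write.csv(
      data.frame(t = sn$time, id = p$id, x = p$x, y = p$y, age = p$age,
                 biomass = p$B, bmax = p$Bmax),
      file.path(dir, paste0("plants_t", tag, ".csv")), row.names = FALSE)
    utils::write.table(sn$O, file.path(dir, paste0("O_t", tag, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.table(sn$W, file.path(dir, paste0("W_t", tag, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
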