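# CSV interchange. All tables use calendar-year labels in files and
# 0-offset internal indices; age is "Y"/"O", habitat "S"/"T". Event
# code dialects (documented in the README):
#   adult:    0 not seen; 1 seen S success; 2 seen S failed; 3 seen S
#             unknown; 4 seen T success; 5 seen T failed; 6 seen T unknown
#   juvenile: 0 not seen; 1 seen breeding S; 2 seen breeding T

ipm_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hsipm_error")))
}

#' Write an IPM dataset to CSV files
#'
#' Writes the five observed tables (`breeding.csv`, `fledglings.csv`,
#' `adult_histories.csv`, `juvenile_histories.csv`, `counts.csv`) in
#' the canonical interchange format.
#'
#' @param dataset an `ipm_dataset`.
#' @param dir output directory (created if missing).
#' @param start_year calendar year of the first breeding season.
#' @return Invisibly, the vector of file paths written.
#' @export
write_dataset <- function(dataset, dir, start_year = 1993) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yr <- function(t) start_year + t - 1L
  lab_age <- c("Y", "O"); lab_hab <- c("S", "T")
  paths <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, path)
  }
  br <- dataset$breeding
  wr(data.frame(year = yr(br$year), age = lab_age[br$age],
                habitat = lab_hab[br$hab], n_monitored = br$R,
                n_successful = br$B), "breeding.csv")
  fl <- dataset$fledglings
  wr(data.frame(year = yr(fl$year), age = lab_age[fl$age],
                habitat = lab_hab[fl$hab], n_sites_known = fl$S,
                n_fledglings = fl$F), "fledglings.csv")
  ah <- dataset$adult_histories
  TT <- dataset$years
  ev <- ah$events
  evc <- matrix("", nrow(ev), TT)
  evc[!is.na(ev)] <- as.character(ev[!is.na(ev)])
  st <- ah$state
  age1 <- ifelse(st <= 4, "Y", "O")
  hab1 <- lab_hab[((st - 1) %/% 2) %% 2 + 1]
  suc1 <- 1L - (st - 1) %% 2
  adf <- data.frame(id = seq_along(ah$first), first_year = yr(ah$first),
                    age_first = age1, habitat_first = hab1,
                    success_first = suc1)
  colnames(evc) <- paste0("y", yr(seq_len(TT)))
  wr(cbind(adf, as.data.frame(evc)), "adult_histories.csv")
  jh <- dataset$juvenile_histories
  wr(data.frame(cohort = yr(jh$cohort), natal_habitat = lab_hab[jh$natal],
                event = jh$event), "juvenile_histories.csv")
  cnt <- dataset$counts
  cdf <- expand.grid(k = 1:4, t = seq_len(TT))
  wr(data.frame(year = yr(cdf$t),
                age = lab_age[(cdf$k > 2) + 1],
                habitat = lab_hab[(cdf$k - 1) %% 2 + 1],
                count = cnt[cbind(cdf$k, cdf$t)]), "counts.csv")
  invisible(paths)
}

#' Read and validate an IPM dataset from CSV files
#'
#' Reads the five canonical tables from a directory, validates headers,
#' event codes and year-range consistency, and returns an
#' `ipm_dataset`. Errors are signalled as distinct condition classes:
#' `hsipm_schema_error`, `hsipm_event_code_error`,
#' `hsipm_year_range_error`.
#'
#' @param dir directory containing the CSV files.
#' @return An `ipm_dataset`.
#' @export
read_dataset <- function(dir) {
  need <- function(name, cols) {
    path <- file.path(dir, name)
    if (!file.exists(path))
      ipm_error(paste0("missing input file: ", path), "hsipm_schema_error")
    df <- read.csv(path, check.names = FALSE)
    miss <- setdiff(cols, colnames(df))
    if (length(miss))
      ipm_error(sprintf("%s: missing columns %s", name,
                        paste(miss, collapse = ", ")), "hsipm_schema_error")
    df
  }
  br <- need("breeding.csv", c("year", "age", "habitat", "n_monitored",
                               "n_successful"))
  fl <- need("fledglings.csv", c("year", "age", "habitat", "n_sites_known",
                                 "n_fledglings"))
  ad <- need("adult_histories.csv", c("id", "first_year", "age_first",
                                      "habitat_first", "success_first"))
  jv <- need("juvenile_histories.csv", c("cohort", "natal_habitat", "event"))
  cn <- need("counts.csv", c("year", "age", "habitat", "count"))

  years <- sort(unique(cn$year))
  start_year <- min(years)
  TT <- length(years)
  if (!identical(years, seq(start_year, start_year + TT - 1)))
    ipm_error("counts.csv must cover a contiguous year range",
              "hsipm_year_range_error")
  to_t <- function(y, what) {
    t <- y - start_year + 1L
    if (any(t < 1 | t > TT))
      ipm_error(sprintf("%s: years outside the count range %d-%d", what,
                        start_year, max(years)), "hsipm_year_range_error")
    t
  }
  dec_age <- function(x, what) {
    out <- match(x, c("Y", "O"))
    if (any(is.na(out)))
      ipm_error(paste0(what, ": age must be Y or O"), "hsipm_schema_error")
    out
  }
  dec_hab <- function(x, what) {
    out <- match(x, c("S", "T"))
    if (any(is.na(out)))
      ipm_error(paste0(what, ": habitat must be S or T"), "hsipm_schema_error")
    out
  }

  breeding <- data.frame(year = to_t(br$year, "breeding.csv"),
                         age = dec_age(br$age, "breeding.csv"),
                         hab = dec_hab(br$habitat, "breeding.csv"),
                         R = br$n_monitored, B = br$n_successful)
  if (any(breeding$B > breeding$R | breeding$B < 0))
    ipm_error("breeding.csv: need 0 <= n_successful <= n_monitored",
              "hsipm_schema_error")
  fledglings <- data.frame(year = to_t(fl$year, "fledglings.csv"),
                           age = dec_age(fl$age, "fledglings.csv"),
                           hab = dec_hab(fl$habitat, "fledglings.csv"),
                           S = fl$n_sites_known, F = fl$n_fledglings)
  if (any(fledglings$F < fledglings$S))
    ipm_error("fledglings.csv: need n_fledglings >= n_sites_known",
              "hsipm_schema_error")

  evcols <- paste0("y", years)
  miss <- setdiff(evcols, colnames(ad))
  if (length(miss))
    ipm_error(paste0("adult_histories.csv: missing event columns ",
                     paste(miss, collapse = ", ")), "hsipm_schema_error")
  first <- to_t(ad$first_year, "adult_histories.csv")
  ev <- matrix(NA_integer_, nrow(ad), TT)
  for (t in seq_len(TT)) {
    col <- ad[[evcols[t]]]
    ok <- !(is.na(col) | col == "")
    if (any(ok)) {
      v <- suppressWarnings(as.integer(col[ok]))
      bad <- is.na(v) | v < 0 | v > 6
      if (any(bad))
        ipm_error(sprintf(
          "adult_histories.csv: invalid adult event code in column %s, row %d (dialect is 0-6)",
          evcols[t], which(ok)[which(bad)[1]]), "hsipm_event_code_error")
      ev[ok, t] <- v
    }
  }
  for (i in seq_len(nrow(ev))) {
    if (first[i] < TT && any(is.na(ev[i, (first[i] + 1):TT])))
      ipm_error(sprintf(
        "adult_histories.csv: bird %s has missing events after first capture",
        ad$id[i]), "hsipm_schema_error")
  }
  a1 <- dec_age(ad$age_first, "adult_histories.csv")
  h1 <- dec_hab(ad$habitat_first, "adult_histories.csv")
  s1 <- ad$success_first
  if (any(!s1 %in% c(0, 1)))
    ipm_error("adult_histories.csv: success_first must be 0 or 1",
              "hsipm_schema_error")
  state <- (a1 - 1L) * 4L + (h1 - 1L) * 2L + ifelse(s1 == 1, 1L, 2L)

  if (any(!jv$event %in% 0:2))
    ipm_error(sprintf(
      "juvenile_histories.csv: invalid juvenile event code in row %d (dialect is 0-2)",
      which(!jv$event %in% 0:2)[1]), "hsipm_event_code_error")
  juvenile <- data.frame(cohort = to_t(jv$cohort, "juvenile_histories.csv"),
                         natal = dec_hab(jv$natal_habitat,
                                         "juvenile_histories.csv"),
                         event = jv$event)
  if (any(juvenile$cohort >= TT))
    ipm_error("juvenile_histories.csv: cohorts must precede the final count year",
              "hsipm_year_range_error")

  counts <- matrix(0L, 4, TT, dimnames = list(CLASS_ORDER, NULL))
  k <- (dec_age(cn$age, "counts.csv") - 1L) * 2L + dec_hab(cn$habitat, "counts.csv")
  counts[cbind(k, to_t(cn$year, "counts.csv"))] <- as.integer(cn$count)
  if (any(counts < 0))
    ipm_error("counts.csv: counts must be non-negative", "hsipm_schema_error")

  structure(list(breeding = breeding, fledglings = fledglings,
                 adult_histories = list(first = first, state = state, events = ev),
                 juvenile_histories = juvenile, counts = counts,
                 years = TT, start_year = start_year),
            class = "ipm_dataset")
}

#' Write a run manifest
#'
#' Records what was run and with what: command, configuration snapshot,
#' seed, package version, input-file MD5 digests, timestamps and
#' convergence flags — one JSON manifest per pipeline run.
#'
#' @param path output path of the manifest JSON.
#' @param command character label of the command/stage set.
#' @param config configuration list (serialised as-is).
#' @param seed master seed.
#' @param inputs character vector of input file paths (digested).
#' @param started,finished POSIXct timestamps.
#' @param convergence optional named flags (e.g. max R-hat, flagged
#'   parameter count).
#' @return Invisibly, the manifest list.
#' @export
run_manifest <- function(path, command, config, seed, inputs = character(0),
                         started = Sys.time(), finished = Sys.time(),
                         convergence = NULL) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  man <- list(
    command = command,
    package_version = as.character(utils::packageVersion("hsipm")),
    seed = seed,
    config = config,
    input_digests = digests,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    convergence = convergence
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(man)
}
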