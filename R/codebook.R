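#' Construct a codebook of comment categories
#'
#' A codebook is the fixed set of content categories used to label comments:
#' each category has an integer `id`, a free-text `description`, and a
#' `polarity` that is either `"positive"` (pro-vaccine / supportive content)
#' or `"anti"` (an anti-vaccine argument theme).
#'
#' @param categories A data frame with columns `id` (integer), `description`
#'   (character) and `polarity` (`"positive"` or `"anti"`).
#' @return A `vax_codebook` tibble.
#' @export
codebook <- function(categories) {
  cb <- as_tibble(categories)
  required <- c("id", "description", "polarity")
  missing_cols <- setdiff(required, names(cb))
  if (length(missing_cols) > 0) {
    abort_schema(paste0("Codebook is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  cb$id <- as.integer(cb$id)
  if (nrow(cb) == 0) abort_validation("Codebook must contain at least one category.")
  if (anyDuplicated(cb$id)) abort_validation("Codebook category ids must be unique.")
  if (is.unsorted(cb$id, strictly = TRUE)) {
    abort_validation("Codebook category ids must be strictly increasing.")
  }
  if (!all(cb$polarity %in% c("positive", "anti"))) {
    abort_validation("Codebook polarity must be 'positive' or 'anti'.")
  }
  structure(cb[required], class = c("vax_codebook", class(cb)))
}

#' The default 15-category vaccine-discourse codebook
#'
#' One positive category (id 0) and fourteen anti-vaccine argument themes
#' (ids 1-14), ordered by their frequency in popular-comment data: personal
#' freedom of choice, distrust of government, safety concerns, efficacy
#' doubts, insufficient testing, criticism of vaccination bragging, claims
#' that public figures received inert injections, conspiracy theories,
#' accusations of paid promotion, downplaying the disease, liability
#' concerns, corporate-profit claims, preference for unproven treatments,
#' and preference for natural immunity.
#'
#' @return A `vax_codebook` tibble with 15 rows.
#' @export
default_codebook <- function() {
  codebook(tibble(
    id = 0:14,
    description = c(
      "Positive attitude toward vaccination",
      "Refuses vaccination as a matter of personal freedom of choice",
      "Distrust of the government",
      "Vaccines are dangerous to health",
      "Vaccines are ineffective",
      "Vaccines are insufficiently tested / developed too quickly",
      "Criticizing people who boast about being vaccinated",
      "Public figures injected with inert substances (e.g., saline)",
      "Conspiracy theories and hidden vaccine effects (e.g., chips)",
      "Poster accused of profiting from encouraging vaccination",
      "COVID-19 is not dangerous to health",
      "No one takes responsibility for vaccine side effects",
      "Vaccines exist only for pharmaceutical-company profit",
      "Better to treat COVID-19 with drugs than to vaccinate",
      "Natural protection methods are better than vaccines"
    ),
    polarity = c("positive", rep("anti", 14))
  ))
}

#' Category ids by polarity
#'
#' @param cb A `vax_codebook`.
#' @return Integer vector of category ids.
#' @export
anti_ids <- function(cb) cb$id[cb$polarity == "anti"]

#' @rdname anti_ids
#' @export
positive_ids <- function(cb) cb$id[cb$polarity == "positive"]

#' Read / write a codebook (JSON or YAML)
#'
#' The on-disk form is a list of objects with keys `id`, `description`,
#' `polarity`. The format is chosen from the file extension
#' (`.json` vs `.yaml`/`.yml`) unless given explicitly.
#'
#' @param path File path.
#' @param format `"json"`, `"yaml"`, or `NULL` to infer from the extension.
#' @return `read_codebook()` returns a `vax_codebook`;
#'   `write_codebook()` returns `path` invisibly.
#' @export
read_codebook <- function(path, format = NULL) {
  format <- format %||% infer_format(path, c(json = "json", yaml = "yaml", yml = "yaml"))
  raw <- switch(format,
    json = jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    yaml = {
      lst <- yaml::read_yaml(path)
      do.call(rbind.data.frame, lapply(lst, as.data.frame))
    },
    abort_config(paste0("Unsupported codebook format: ", format))
  )
  codebook(raw)
}

#' @rdname read_codebook
#' @param cb A `vax_codebook` to write.
#' @export
write_codebook <- function(cb, path, format = NULL) {
  format <- format %||% infer_format(path, c(json = "json", yaml = "yaml", yml = "yaml"))
  df <- as.data.frame(cb)
  switch(format,
    json = jsonlite::write_json(df, path, auto_unbox = TRUE, pretty = TRUE),
    yaml = yaml::write_yaml(
      lapply(seq_len(nrow(df)), function(i) as.list(df[i, ])), path),
    abort_config(paste0("Unsupported codebook format: ", format))
  )
  invisible(path)
}

infer_format <- function(path, map) {
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% names(map)) {
    abort_config(paste0("Cannot infer file format from extension '.", ext, "'"))
  }
  unname(map[[ext]])
}

#' Default per-category keyword pools
#'
#' Six keywords per category, taken from the published keyword lists of the
#' reference annotated corpus of 1,000 top comments. Used as the default
#' planted-keyword pools of the synthetic corpus generator and useful as a
#' fixture for keyword-recovery experiments.
#'
#' @return Named list (names = category ids "0".."14") of character vectors.
#' @export
default_keyword_pools <- function() {
  list(
    `0`  = c("vaccination", "vaccinate", "dose", "get", "people", "second"),
    `1`  = c("vaccinate", "choice", "freedom", "never", "get", "everyone"),
    `2`  = c("people", "lie", "gift", "anymore", "pinocchio", "propaganda"),
    `3`  = c("die", "death", "people", "heart", "get", "complication"),
    `4`  = c("protection", "data", "infect", "dose", "basis", "get"),
    `5`  = c("experiment", "test", "medical", "vaccine", "pig", "guinea"),
    `6`  = c("brag", "understand", "advertise", "sympathize", "publicly", "celebrity"),
    `7`  = c("vitamin", "saline", "syringe", "placebo", "teleconsultation", "inoculate"),
    `8`  = c("normality", "cover", "weirdos", "warning", "victim", "unprecedented"),
    `9`  = c("pay", "traitor", "stink", "much", "advertising", "ad"),
    `10` = c("virus", "alive", "similar", "global", "evolution", "topic"),
    `11` = c("responsibility", "raid", "composition", "manufacturer", "responsible", "compensation"),
    `12` = c("pharmaceutical", "viruses", "interested", "diet", "widely", "revenue"),
    `13` = c("medication", "amantadine", "condition", "mess", "authoritarianism", "treatment"),
    `14` = c("natural", "vaccinophobia", "sugar", "recovered", "preach", "junk")
  )
}
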