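#' Construct an item bank
#'
#' An item bank is the measurement model of the adaptive test: a
#' collection of [pcm_item()]s grouped by domain. Item ids must be unique.
#'
#' @param items List of [pcm_item()] objects.
#' @return An object of class `item_bank`.
#' @export
item_bank <- function(items) {
  if (!length(items) || !all(vapply(items, is_pcm_item, logical(1)))) {
    stop("'items' must be a non-empty list of pcm_item objects",
         call. = FALSE)
  }
  ids <- vapply(items, function(it) it$item_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate item_id in bank: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(items) <- ids
  structure(list(items = items), class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  doms <- bank_domains(x)
  cat(sprintf("Item bank: %d items across %d domain%s\n",
              length(x$items), length(doms),
              if (length(doms) == 1L) "" else "s"))
  for (d in doms) {
    n <- length(bank_items(x, d))
    cat(sprintf("  %s: %d items\n", d, n))
  }
  invisible(x)
}

#' Domains present in an item bank
#' @param bank An [item_bank()].
#' @return Character vector of domain ids, in first-appearance order.
#' @export
bank_domains <- function(bank) {
  unique(vapply(bank$items, function(it) it$domain_id, character(1)))
}

#' Items of one domain
#' @param bank An [item_bank()].
#' @param domain_id Domain to extract.
#' @return List of [pcm_item()]s.
#' @export
bank_items <- function(bank, domain_id) {
  keep <- vapply(bank$items, function(it) it$domain_id == domain_id,
                 logical(1))
  bank$items[keep]
}

#' Read an item bank from CSV or JSON
#'
#' CSV layout: columns `item_id`, `domain_id`, `b1..bK`, with empty
#' trailing cells for items having fewer than `K` steps. JSON layout: an
#' array of objects with `item_id`, `domain_id` and a `thresholds` array.
#' The format is chosen by file extension (`.json` vs anything else).
#'
#' @param path File path.
#' @return An [item_bank()].
#' @export
read_item_bank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    items <- lapply(recs, function(r) {
      pcm_item(r$item_id, r$domain_id, unlist(r$thresholds))
    })
    return(item_bank(items))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
  bcols <- bcols[order(as.integer(sub("^b", "", bcols)))]
  if (!all(c("item_id", "domain_id") %in% names(df)) || !length(bcols)) {
    stop("bank CSV needs columns item_id, domain_id, b1..bK", call. = FALSE)
  }
  items <- lapply(seq_len(nrow(df)), function(i) {
    b <- as.numeric(df[i, bcols])
    pcm_item(df$item_id[i], df$domain_id[i], b[!is.na(b)])
  })
  item_bank(items)
}

#' Write an item bank to CSV or JSON
#'
#' Inverse of [read_item_bank()]; the CSV pads items with fewer steps
#' with empty cells.
#'
#' @param bank An [item_bank()].
#' @param path Destination; `.json` selects JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- lapply(unname(bank$items), function(it) {
      list(item_id = it$item_id, domain_id = it$domain_id,
           thresholds = it$thresholds)
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  K <- max(vapply(bank$items, function(it) length(it$thresholds), integer(1)))
  rows <- lapply(unname(bank$items), function(it) {
    b <- c(it$thresholds, rep(NA_real_, K - length(it$thresholds)))
    c(list(item_id = it$item_id, domain_id = it$domain_id),
      stats::setNames(as.list(b), paste0("b", seq_len(K))))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
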