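#' Reading stores and patient identification
#'
#' Storage is a framework hot spot: monitoring code talks to an abstract
#' reading-store contract and concrete back-ends plug in behind it. Two
#' back-ends ship — an in-memory store and a durable JSON-lines store — plus
#' a buffering wrapper implementing a cached-storage strategy (readings
#' appended while the back-end is unavailable are buffered and flushed on
#' recovery). All back-ends satisfy the same observable contract:
#' read-your-writes, timestamp-ordered query results over half-open time
#' ranges `[from, to)`, and idempotent appends (a second append of an
#' identical (patient, sensor, timestamp, value) tuple stores nothing new).
#' Readings are immutable once appended.
#'
#' @name storage
NULL

reading_key <- function(df) {
  paste(df$patient_id, df$sensor_id, df$timestamp, df$value, sep = "\r")
}

empty_readings <- function() {
  data.frame(patient_id = character(), sensor_id = character(),
             timestamp = numeric(), value = numeric(),
             signal_quality = character(), activity = character(),
             stringsAsFactors = FALSE)
}

#' In-memory reading store
#' @export
MemoryStore <- R6::R6Class("MemoryStore",
  public = list(
    #' @description Create an empty store.
    initialize = function() {
      private$data <- empty_readings()
    },

    #' @description Append readings (one or more rows). Idempotent on
    #'   identical (patient, sensor, timestamp, value) tuples.
    #' @param readings data frame in the canonical reading layout.
    #' @return receipt list: `accepted` (rows stored), `duplicates`.
    append = function(readings) {
      validate_readings(readings, ordered = FALSE)
      keys <- reading_key(readings)
      fresh <- !(keys %in% reading_key(private$data)) & !duplicated(keys)
      private$data <- rbind(private$data,
                            readings[fresh, names(empty_readings())])
      list(accepted = sum(fresh), duplicates = sum(!fresh))
    },

    #' @description Query readings in the half-open range `[from, to)`,
    #'   ordered by timestamp.
    #' @param patient_id,sensor_id stream selectors; `NULL` selects all.
    #' @param from,to numeric bounds, `from <= to`.
    #' @return data frame of readings.
    query = function(patient_id = NULL, sensor_id = NULL,
                     from = -Inf, to = Inf) {
      if (from > to)
        stop("inverted time range: from > to", call. = FALSE)
      d <- private$data
      if (!is.null(patient_id)) d <- d[d$patient_id %in% patient_id, ]
      if (!is.null(sensor_id)) d <- d[d$sensor_id %in% sensor_id, ]
      d <- d[d$timestamp >= from & d$timestamp < to, ]
      d <- d[order(d$timestamp), ]
      rownames(d) <- NULL
      d
    },

    #' @description Latest stored timestamp for a stream (the high-water
    #'   mark used to avoid re-processing readings).
    #' @param patient_id,sensor_id stream selectors; `NULL` selects all.
    #' @return numeric timestamp, `-Inf` for an empty stream.
    high_water_mark = function(patient_id = NULL, sensor_id = NULL) {
      d <- self$query(patient_id, sensor_id)
      if (nrow(d) == 0) -Inf else max(d$timestamp)
    },

    #' @description Number of stored readings.
    count = function() nrow(private$data)
  ),
  private = list(data = NULL)
)

#' Durable JSON-lines reading store
#'
#' Same contract as [MemoryStore], persisted one reading per line to a
#' JSON-lines file. Existing content is loaded at construction, so a store
#' reopened on the same path sees all previously appended readings.
#'
#' @export
JsonlStore <- R6::R6Class("JsonlStore",
  inherit = MemoryStore,
  public = list(
    #' @description Open (or create) a store at `path`.
    #' @param path JSON-lines file path.
    initialize = function(path) {
      super$initialize()
      private$path <- path
      if (file.exists(path) && file.size(path) > 0) {
        existing <- read_readings_jsonl(path)
        super$append(existing)
      }
    },

    #' @description Append readings; accepted rows are written through to
    #'   the file.
    #' @param readings data frame in the canonical reading layout.
    #' @return receipt list: `accepted`, `duplicates`.
    append = function(readings) {
      keys <- reading_key(readings)
      fresh <- readings[!(keys %in% private$seen_keys()) &
                          !duplicated(keys), , drop = FALSE]
      receipt <- super$append(readings)
      if (nrow(fresh)) {
        con <- file(private$path, "a")
        on.exit(close(con))
        for (i in seq_len(nrow(fresh)))
          writeLines(jsonlite::toJSON(as.list(fresh[i, ]),
                                      auto_unbox = TRUE, digits = NA), con)
      }
      receipt
    }
  ),
  private = list(
    path = NULL,
    seen_keys = function() reading_key(self$query())
  )
)

#' Buffering wrapper: cached-storage strategy
#'
#' Wraps any reading store. While the back-end is flagged unavailable,
#' appends are buffered locally instead of failing; when availability
#' returns, the buffer is flushed in append order. Queries require the
#' back-end to be available.
#'
#' @export
BufferedStore <- R6::R6Class("BufferedStore",
  public = list(
    #' @description Wrap a back-end store.
    #' @param backend a store satisfying the reading-store contract.
    initialize = function(backend) {
      private$backend <- backend
      private$buffer <- empty_readings()
    },

    #' @description Mark the back-end up or down.
    #' @param up logical. Coming back up flushes the buffer.
    set_available = function(up) {
      private$up <- isTRUE(up)
      if (private$up) self$flush()
      invisible(self)
    },

    #' @description Flush buffered readings to the back-end (no-op when
    #'   down or empty).
    flush = function() {
      if (private$up && nrow(private$buffer)) {
        private$backend$append(private$buffer)
        private$buffer <- empty_readings()
      }
      invisible(self)
    },

    #' @description Append readings, buffering while the back-end is down.
    #' @param readings data frame in the canonical reading layout.
    #' @return receipt: back-end receipt, or `list(buffered = n)`.
    append = function(readings) {
      validate_readings(readings, ordered = FALSE)
      if (!private$up) {
        private$buffer <- rbind(private$buffer,
                                readings[, names(empty_readings())])
        return(list(buffered = nrow(readings)))
      }
      self$flush()
      private$backend$append(readings)
    },

    #' @description Query the back-end (see [MemoryStore]).
    #' @param patient_id,sensor_id,from,to as in the contract.
    query = function(patient_id = NULL, sensor_id = NULL,
                     from = -Inf, to = Inf) {
      if (!private$up)
        stop("storage back-end unavailable", call. = FALSE)
      self$flush()
      private$backend$query(patient_id, sensor_id, from, to)
    },

    #' @description High-water mark of the back-end.
    #' @param patient_id,sensor_id stream selectors.
    high_water_mark = function(patient_id = NULL, sensor_id = NULL) {
      private$backend$high_water_mark(patient_id, sensor_id)
    },

    #' @description Readings currently buffered (back-end down).
    buffered = function() nrow(private$buffer)
  ),
  private = list(backend = NULL, buffer = NULL, up = TRUE)
)

# plugin registry: back-end name -> factory(...)
store_registry <- new.env(parent = emptyenv())

#' Register a storage back-end factory
#'
#' The hot-spot mechanism: applications add back-ends by name without
#' touching monitoring code. `"memory"` and `"jsonl"` are pre-registered.
#'
#' @param name back-end name.
#' @param factory function returning a store object.
#' @return `name`, invisibly.
#' @export
register_store_backend <- function(name, factory) {
  stopifnot(is.character(name), is.function(factory))
  assign(name, factory, envir = store_registry)
  invisible(name)
}

#' Instantiate a registered storage back-end
#' @param name registered back-end name.
#' @param ... passed to the factory.
#' @return a store object.
#' @export
create_store <- function(name, ...) {
  if (!exists(name, envir = store_registry, inherits = FALSE))
    stop("unknown storage back-end '", name, "'; registered: ",
         paste(ls(store_registry), collapse = ", "), call. = FALSE)
  get(name, envir = store_registry)(...)
}

#' List registered storage back-ends
#' @return character vector of names.
#' @export
store_backends <- function() ls(store_registry)

.onLoad <- function(libname, pkgname) {
  register_store_backend("memory", function() MemoryStore$new())
  register_store_backend("jsonl", function(path) JsonlStore$new(path))
}

#' Load a patient registry
#'
#' CSV (columns `patient_id`, `rfid_tag`, `name`, `age`, `sex`, `location`)
#' or JSON array of profile objects. Duplicate patient ids or RFID tags are
#' an integrity error at load time.
#'
#' @param path registry file.
#' @return data frame of patient profiles.
#' @export
load_patient_registry <- function(path) {
  if (!file.exists(path))
    stop("patient registry not found: ", path, call. = FALSE)
  reg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  }
  required <- c("patient_id", "rfid_tag")
  if (!all(required %in% names(reg)))
    stop("registry must have patient_id and rfid_tag columns", call. = FALSE)
  reg$rfid_tag <- toupper(reg$rfid_tag)
  if (anyDuplicated(reg$patient_id))
    stop("integrity error: duplicate patient_id in registry", call. = FALSE)
  if (anyDuplicated(reg$rfid_tag))
    stop("integrity error: duplicate rfid_tag in registry", call. = FALSE)
  reg
}

#' Resolve an RFID bracelet tag to a patient profile
#'
#' @param tag hex tag string (case-insensitive).
#' @param registry data frame from [load_patient_registry()].
#' @return the matching registry row, or `NULL` when the tag is unknown
#'   (callers quarantine the associated reading rather than dropping it).
#' @export
resolve_identity <- function(tag, registry) {
  hit <- registry[registry$rfid_tag == toupper(tag), , drop = FALSE]
  if (nrow(hit) == 0) return(NULL)
  as.list(hit[1, ])
}

#' Read readings from a JSON-lines file
#' @param path file with one reading JSON object per line.
#' @return data frame in the canonical reading layout.
#' @export
read_readings_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_readings())
  rows <- lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df$timestamp <- as.numeric(df$timestamp)
  df$value <- as.numeric(df$value)
  df[, names(empty_readings())]
}

#' Write readings to CSV
#' @param readings canonical readings data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_readings_csv <- function(readings, path) {
  utils::write.csv(readings[, names(empty_readings())], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read readings from CSV
#' @param path CSV with the canonical reading columns.
#' @return data frame in the canonical reading layout.
#' @export
read_readings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_readings(df)
  df[, names(empty_readings())]
}
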