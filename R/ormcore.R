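# Connection handling, lazy schema reflection and the deferred query builder.
#
# Handles are environments so that per-handle caches (reflected tables) and
# instrumentation counters (reflect_count, query_count) persist across calls
# without global state. All user-supplied values reach the backend as bound
# parameters; identifiers are validated against the reflected column list
# and quoted.

new_db_handle <- function(con, uri, name) {
  h <- new.env(parent = emptyenv())
  h$con <- con
  h$uri <- uri
  h$name <- name
  h$tables <- new.env(parent = emptyenv())
  h$reflect_count <- 0L
  h$query_count <- 0L
  class(h) <- "ucsc_db"
  h
}

#' Connect to an annotation database
#'
#' Opens a read-only handle to a database whose tables follow UCSC-style
#' schemas. The locator is either a plain file path (or `sqlite://` URI) to
#' an embedded SQLite database — the form used throughout the test fixtures
#' — or a `mysql://host[:port]/dbname` URI for a server mirror, which
#' requires the optional RMariaDB driver. Several handles may be open at
#' once and are fully independent; no table is reflected until first use.
#'
#' @param uri Connection locator as above.
#' @param name Label for the database (defaults to the file or database
#'   name); used by joiner-schema association lookup.
#' @return An object of class `ucsc_db`.
#' @seealso [table_handle()], [disconnect()]
#' @export
connect <- function(uri, name = NULL) {
  if (!is_scalar_string(uri) || !nzchar(uri)) {
    stop_user("connection locator must be a non-empty string")
  }
  has_scheme <- grepl("^[A-Za-z][A-Za-z0-9+.-]*://", uri)
  scheme <- if (has_scheme) sub("://.*$", "", uri) else NA_character_
  if (!is.na(scheme) && scheme == "mysql") {
    if (!requireNamespace("RMariaDB", quietly = TRUE)) {
      stop_user("mysql:// connections require the RMariaDB driver, which is not installed")
    }
    rest <- sub("^mysql://", "", uri)
    slash <- regexpr("/", rest, fixed = TRUE)
    if (slash < 0) stop_user("mysql URI '%s' lacks a database name", uri)
    hostport <- substr(rest, 1L, slash - 1L)
    dbname <- substr(rest, slash + 1L, nchar(rest))
    host <- sub(":.*$", "", hostport)
    port <- if (grepl(":", hostport)) as.integer(sub("^.*:", "", hostport)) else 3306L
    con <- DBI::dbConnect(RMariaDB::MariaDB(), host = host, port = port,
                          dbname = dbname, username = "genome")
    return(new_db_handle(con, uri, name %||% dbname))
  }
  if (!is.na(scheme) && scheme != "sqlite") {
    stop_user("unsupported connection scheme '%s' (use a file path, sqlite:// or mysql://)",
              scheme)
  }
  path <- if (is.na(scheme)) uri else sub("^sqlite://", "", uri)
  if (path != ":memory:" && !file.exists(path)) {
    stop_user("database file '%s' does not exist", path)
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  default_name <- if (path == ":memory:") "memory" else {
    tools::file_path_sans_ext(basename(path))
  }
  new_db_handle(con, uri, name %||% default_name)
}

#' @rdname connect
#' @param db A `ucsc_db` handle.
#' @export
disconnect <- function(db) {
  stopifnot(inherits(db, "ucsc_db"))
  DBI::dbDisconnect(db$con)
  invisible(NULL)
}

#' @export
print.ucsc_db <- function(x, ...) {
  cat(sprintf("<ucsc_db '%s' at %s; %d reflected table(s)>\n",
              x$name, x$uri, length(ls(x$tables))))
  invisible(x)
}

# Positional-column families, in order of preference: BED-like annotation
# tables, genePred tables, then alignment (PSL-style) tables.
.positional_triples <- list(c("chrom", "chromStart", "chromEnd"),
                            c("chrom", "txStart", "txEnd"),
                            c("tName", "tStart", "tEnd"))

#' Reflect a table
#'
#' Fetches the column metadata of `name` from the live schema on first use
#' and caches the handle: a second call performs no schema read. The handle
#' records whether a `bin` column exists (enabling automatic bin-index
#' acceleration) and which positional column triple the table carries
#' (`chrom`/`chromStart`/`chromEnd`, genePred `txStart`/`txEnd`, or
#' PSL-style `tName`/`tStart`/`tEnd`).
#'
#' @param db A [connect()] handle.
#' @param name Table name.
#' @return An object of class `ucsc_table`.
#' @export
table_handle <- function(db, name) {
  stopifnot(inherits(db, "ucsc_db"))
  if (!is_scalar_string(name)) stop_user("table name must be a string")
  cached <- db$tables[[name]]
  if (!is.null(cached)) return(cached)
  if (!DBI::dbExistsTable(db$con, name)) {
    stop_user("unknown table '%s' (available: %s)", name,
              paste(sort(DBI::dbListTables(db$con)), collapse = ", "))
  }
  db$reflect_count <- db$reflect_count + 1L
  pk <- NA_character_
  if (methods::is(db$con, "SQLiteConnection")) {
    info <- DBI::dbGetQuery(db$con, sprintf("PRAGMA table_info(%s)",
                                            DBI::dbQuoteIdentifier(db$con, name)))
    columns <- data.frame(name = info$name, type = info$type,
                          stringsAsFactors = FALSE)
    if (any(info$pk > 0)) pk <- info$name[info$pk > 0][1L]
  } else {
    res <- DBI::dbSendQuery(db$con, sprintf("SELECT * FROM %s LIMIT 0",
                                            DBI::dbQuoteIdentifier(db$con, name)))
    ci <- DBI::dbColumnInfo(res)
    DBI::dbClearResult(res)
    columns <- data.frame(name = ci$name, type = as.character(ci$type),
                          stringsAsFactors = FALSE)
  }
  positional <- NULL
  for (triple in .positional_triples) {
    if (all(triple %in% columns$name)) {
      positional <- triple
      break
    }
  }
  t <- structure(list(db = db,
                      name = name,
                      columns = columns,
                      has_bin = "bin" %in% columns$name,
                      positional = positional,
                      default_order = if (!is.na(pk)) pk else columns$name[1L]),
                 class = "ucsc_table")
  assign(name, t, envir = db$tables)
  t
}

#' @export
print.ucsc_table <- function(x, ...) {
  cat(sprintf("<ucsc_table '%s'.%s: %d columns%s%s>\n",
              x$db$name, x$name, nrow(x$columns),
              if (x$has_bin) ", bin-indexed" else "",
              if (!is.null(x$positional)) {
                sprintf(", positional (%s)", paste(x$positional, collapse = ","))
              } else ""))
  invisible(x)
}

check_field <- function(t, field) {
  if (!is_scalar_string(field) || !(field %in% t$columns$name)) {
    stop_user("unknown field '%s' in table '%s' (columns: %s)",
              as.character(field)[1L], t$name, paste(t$columns$name, collapse = ", "))
  }
  invisible(field)
}

# ---- query expressions -------------------------------------------------

new_query <- function(t) {
  structure(list(table = t,
                 filters = list(),
                 projection = NULL,
                 ordering = list(),
                 n_limit = NULL,
                 n_offset = NULL,
                 grouping = NULL),
            class = "ucsc_query")
}

as_query <- function(x) {
  if (inherits(x, "ucsc_query")) return(x)
  if (inherits(x, "ucsc_table")) return(new_query(x))
  stop_user("expected a table handle or query expression")
}

#' Chainable query clauses
#'
#' Each clause returns a new immutable query expression; no backend query is
#' issued until a terminal ([fetch_all()], [fetch_first()], [count_rows()])
#' runs, at which point exactly one SQL statement is assembled from all
#' accumulated clauses. All clauses conjoin (AND); there is no OR surface.
#' Columns named in `select`/`order_by`/`group` are validated against the
#' reflected schema before execution; values given to `where()` are bound
#' parameters, never interpolated.
#'
#' @param x A `ucsc_table` or `ucsc_query`.
#' @param ... For `select()`/`group()`: column names (character). For
#'   `where()`: one binding per `?` placeholder.
#' @param condition A SQL condition fragment with `?` placeholders.
#' @param column Column to order by.
#' @param direction `"asc"` or `"desc"`.
#' @param n,offset Row limit and optional offset.
#' @return A new `ucsc_query`.
#' @examples
#' \dontrun{
#' tbl <- table_handle(db, "snpToy")
#' where(select(tbl, "name"), "strand = ?", "+")
#' }
#' @name query-chain
NULL

#' @rdname query-chain
#' @export
select <- function(x, ...) UseMethod("select")

#' @export
select.ucsc_table <- function(x, ...) select(new_query(x), ...)

#' @export
select.ucsc_query <- function(x, ...) {
  cols <- as.character(unlist(list(...)))
  for (col in cols) check_field(x$table, col)
  x$projection <- c(x$projection, cols)
  x
}

#' @rdname query-chain
#' @export
where <- function(x, condition, ...) UseMethod("where")

#' @export
where.ucsc_table <- function(x, condition, ...) where(new_query(x), condition, ...)

#' @export
where.ucsc_query <- function(x, condition, ...) {
  if (!is_scalar_string(condition)) stop_user("where() condition must be a string")
  params <- list(...)
  n_ph <- lengths(regmatches(condition, gregexpr("?", condition, fixed = TRUE)))
  if (n_ph != length(params)) {
    stop_user("where() condition has %d placeholder(s) but %d binding(s) were supplied",
              n_ph, length(params))
  }
  x$filters <- c(x$filters, list(list(sql = condition, params = params)))
  x
}

#' @rdname query-chain
#' @export
order_by <- function(x, column, direction = c("asc", "desc")) UseMethod("order_by")

#' @export
order_by.ucsc_table <- function(x, column, direction = c("asc", "desc")) {
  order_by(new_query(x), column, direction)
}

#' @export
order_by.ucsc_query <- function(x, column, direction = c("asc", "desc")) {
  direction <- match.arg(direction)
  check_field(x$table, column)
  x$ordering <- c(x$ordering, list(c(column, direction)))
  x
}

#' @rdname query-chain
#' @export
limit <- function(x, n, offset = NULL) UseMethod("limit")

#' @export
limit.ucsc_table <- function(x, n, offset = NULL) limit(new_query(x), n, offset)

#' @export
limit.ucsc_query <- function(x, n, offset = NULL) {
  if (!is_whole(n) || n < 0) stop_user("limit must be a non-negative whole number")
  x$n_limit <- n
  if (!is.null(offset)) {
    if (!is_whole(offset) || offset < 0) stop_user("offset must be a non-negative whole number")
    x$n_offset <- offset
  }
  x
}

#' @rdname query-chain
#' @export
group <- function(x, ...) UseMethod("group")

#' @export
group.ucsc_table <- function(x, ...) group(new_query(x), ...)

#' @export
group.ucsc_query <- function(x, ...) {
  cols <- as.character(unlist(list(...)))
  for (col in cols) check_field(x$table, col)
  x$grouping <- c(x$grouping, cols)
  x
}

#' Filter to features overlapping / contained in a genomic interval
#'
#' `with_interval()` restricts a positional table to rows whose span
#' overlaps `iv` (shares at least one base, half-open semantics):
#' `chrom == iv$chrom AND start < iv$end AND end > iv$start`.
#' `with_interval_excl()` instead keeps only rows lying completely within
#' `iv`. When the table has a `bin` column, a `bin IN (...)` clause over
#' [bins_overlapping()] is added automatically; by the bin-scheme soundness
#' property this is a pure optimization and never changes the result set
#' (`use_bin = FALSE` drops it, which exists to make that claim testable).
#'
#' @param x A `ucsc_table` with positional columns, or a query on one.
#' @param iv A [GenomicInterval] (internal 0-based half-open convention;
#'   use [parse_interval()] for browser-style strings).
#' @param use_bin Add the bin-index clause when available?
#' @return A `ucsc_query`.
#' @export
with_interval <- function(x, iv, use_bin = TRUE) {
  .interval_query(x, iv, use_bin, excl = FALSE)
}

#' @rdname with_interval
#' @export
with_interval_excl <- function(x, iv, use_bin = TRUE) {
  .interval_query(x, iv, use_bin, excl = TRUE)
}

.interval_query <- function(x, iv, use_bin, excl) {
  q <- as_query(x)
  stopifnot(inherits(iv, "GenomicInterval"))
  t <- q$table
  if (is.null(t$positional)) {
    stop_user("table '%s' has no recognized positional columns; interval queries are not available",
              t$name)
  }
  con <- t$db$con
  qi <- function(col) DBI::dbQuoteIdentifier(con, col)
  chrom_col <- t$positional[1L]
  start_col <- t$positional[2L]
  end_col <- t$positional[3L]
  add <- function(q, sql, params) {
    q$filters <- c(q$filters, list(list(sql = sql, params = params)))
    q
  }
  q <- add(q, sprintf("%s = ?", qi(chrom_col)), list(iv$chrom))
  if (excl) {
    q <- add(q, sprintf("%s >= ?", qi(start_col)), list(iv$start))
    q <- add(q, sprintf("%s <= ?", qi(end_col)), list(iv$end))
  } else {
    q <- add(q, sprintf("%s < ?", qi(start_col)), list(iv$end))
    q <- add(q, sprintf("%s > ?", qi(end_col)), list(iv$start))
  }
  if (isTRUE(use_bin) && t$has_bin) {
    bins <- bins_overlapping(iv$start, iv$end)
    ph <- paste(rep("?", length(bins)), collapse = ", ")
    q <- add(q, sprintf("%s IN (%s)", qi("bin"), ph), as.list(bins))
  }
  q
}

# ---- execution ---------------------------------------------------------

build_select <- function(q) {
  t <- q$table
  con <- t$db$con
  qi <- function(col) DBI::dbQuoteIdentifier(con, col)
  cols <- if (is.null(q$projection)) "*" else {
    paste(vapply(unique(q$projection), function(c) as.character(qi(c)), ""),
          collapse = ", ")
  }
  sql <- sprintf("SELECT %s FROM %s", cols, qi(t$name))
  params <- list()
  if (length(q$filters)) {
    sql <- paste(sql, "WHERE",
                 paste(sprintf("(%s)", vapply(q$filters, `[[`, "", "sql")),
                       collapse = " AND "))
    params <- do.call(c, lapply(q$filters, `[[`, "params"))
  }
  if (!is.null(q$grouping)) {
    sql <- paste(sql, "GROUP BY",
                 paste(vapply(unique(q$grouping), function(c) as.character(qi(c)), ""),
                       collapse = ", "))
  }
  ordering <- q$ordering
  # Deterministic ordering: tiebreak on the primary key (or first column)
  # unless grouping makes that column invalid.
  if (is.null(q$grouping)) {
    ordered_cols <- vapply(ordering, `[[`, "", 1L)
    if (!(t$default_order %in% ordered_cols) &&
        (is.null(q$projection) || t$default_order %in% q$projection)) {
      ordering <- c(ordering, list(c(t$default_order, "asc")))
    }
  }
  if (length(ordering)) {
    sql <- paste(sql, "ORDER BY",
                 paste(vapply(ordering, function(o) {
                   sprintf("%s %s", qi(o[1L]), toupper(o[2L]))
                 }, ""), collapse = ", "))
  }
  if (!is.null(q$n_limit)) {
    sql <- paste(sql, "LIMIT", format(q$n_limit, scientific = FALSE))
    if (!is.null(q$n_offset)) {
      sql <- paste(sql, "OFFSET", format(q$n_offset, scientific = FALSE))
    }
  }
  list(sql = sql, params = params)
}

run_sql <- function(db, sql, params) {
  db$query_count <- db$query_count + 1L
  if (length(params)) {
    DBI::dbGetQuery(db$con, sql, params = unname(params))
  } else {
    DBI::dbGetQuery(db$con, sql)
  }
}

#' Execute a query
#'
#' Terminal operations: `fetch_all()` returns every matching row as a
#' data.frame (storage types preserved); `fetch_first()` returns the first
#' row under deterministic ordering — primary key if the table has one, else
#' the first reflected column — as a `ucsc_record` whose `$`/`[[` raise an
#' error for unknown fields, or `NULL` when nothing matches; `count_rows()`
#' returns the matching row count. Each terminal issues exactly one backend
#' query.
#'
#' @param x A `ucsc_table` or `ucsc_query`.
#' @return See above.
#' @export
fetch_all <- function(x) {
  q <- as_query(x)
  b <- build_select(q)
  run_sql(q$table$db, b$sql, b$params)
}

#' @rdname fetch_all
#' @export
fetch_first <- function(x) {
  df <- fetch_all(limit(as_query(x), 1))
  if (nrow(df) == 0L) return(NULL)
  new_record(df[1L, , drop = FALSE])
}

#' @rdname fetch_all
#' @export
count_rows <- function(x) {
  q <- as_query(x)
  b <- build_select(q)
  sql <- sprintf("SELECT COUNT(*) AS n FROM (%s)", b$sql)
  run_sql(q$table$db, sql, b$params)$n
}

new_record <- function(row) {
  structure(as.list(row), class = "ucsc_record")
}

#' @export
`$.ucsc_record` <- function(x, name) {
  fields <- names(unclass(x))
  if (!(name %in% fields)) {
    stop_user("record has no field '%s' (fields: %s)", name,
              paste(fields, collapse = ", "))
  }
  .subset2(x, name)
}

#' @export
`[[.ucsc_record` <- function(x, i, ...) {
  if (is.character(i) && !(i %in% names(unclass(x)))) {
    stop_user("record has no field '%s' (fields: %s)", i,
              paste(names(unclass(x)), collapse = ", "))
  }
  .subset2(x, i)
}

#' @export
print.ucsc_record <- function(x, ...) {
  f <- unclass(x)
  cat("<record>\n")
  for (n in names(f)) cat(sprintf("  %s: %s\n", n, paste(format(f[[n]]), collapse = ",")))
  invisible(x)
}

#' Find records by field value
#'
#' `find_by()` returns the first record whose `field` equals `value`
#' (deterministic ordering as in [fetch_first()]), or `NULL` when nothing
#' matches. `find_all_by()` returns all matches as a data.frame.
#'
#' @param t A `ucsc_table`.
#' @param field Reflected column name.
#' @param value Value to match (bound parameter).
#' @return A `ucsc_record` or `NULL`; a data.frame for `find_all_by()`.
#' @export
find_by <- function(t, field, value) {
  fetch_first(.eq_query(t, field, value))
}

#' @rdname find_by
#' @export
find_all_by <- function(t, field, value) {
  fetch_all(.eq_query(t, field, value))
}

.eq_query <- function(t, field, value) {
  q <- as_query(t)
  check_field(q$table, field)
  con <- q$table$db$con
  where(q, sprintf("%s = ?", DBI::dbQuoteIdentifier(con, field)), value)
}
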