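#' Configuration for the synthetic-note generator
#'
#' The generator emulates the sectional structure and annotation statistics of
#' real Chinese clinical notes: about 22 medical entities and 7 temporal
#' expressions per note spread over the standard sections, and a roughly
#' 68/32 split between entities indexed to time nodes and to time intervals.
#' Surface text is template-generated pseudo-clinical prose: every entity is
#' planted by a positional grammar template whose surface pattern determines
#' its relation (a date directly governing the entity means SIMULTANEOUS, a
#' "术后"-style connective after a dated event means AFTER, a "之前" pattern
#' means BEFORE, and an entity in a sentence without any date inherits its
#' section's anchor relation), so gold indices are recoverable by
#' construction.
#'
#' @param mean_entities Mean medical entities per note (default 22).
#' @param mean_tes Mean temporal-expression mentions per note, including the
#'   admission and discharge mentions (default 7).
#' @param node_mix Target fraction of entities indexed to time nodes
#'   (default 0.68; the complement goes to intervals).
#' @param label_noise Probability that an entity's gold index is re-planted to
#'   a timeline ID unreachable from its section's candidate times (default 0).
#' @param optional_section_prob Probability that each optional section
#'   (Personal history, Assistant examination, Preliminary diagnosis) is
#'   drawn into a note (default 0.5).
#' @return An object of class `mt_generator_config`.
#' @export
generator_config <- function(mean_entities = 22, mean_tes = 7,
                             node_mix = 0.68, label_noise = 0,
                             optional_section_prob = 0.5) {
  stopifnot(mean_entities > 0, mean_tes >= 2,
            node_mix >= 0, node_mix <= 1,
            label_noise >= 0, label_noise <= 1)
  structure(list(
    mean_entities = mean_entities,
    mean_tes = mean_tes,
    node_mix = node_mix,
    label_noise = label_noise,
    optional_section_prob = optional_section_prob
  ), class = "mt_generator_config")
}

#' @export
print.mt_generator_config <- function(x, ...) {
  cat("<mt_generator_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

entity_vocabulary <- function() {
  c("发热", "头痛", "恶心", "呕吐", "腹痛", "咳嗽", "腰痛", "乏力", "水肿",
    "胸闷", "气促", "血尿", "贫血", "感染", "结石", "头晕", "心悸", "黄疸",
    "高血压", "糖尿病", "蛋白尿", "肺炎", "尿路感染", "低钾血症", "胆囊结石")
}

procedure_vocabulary <- function() {
  c("血液透析", "碎石术", "置管术", "刮宫术", "输液治疗", "抗感染治疗",
    "补液治疗", "引流术")
}

# ---------------------------------------------------------------------------
# note builder: accumulates text while recording standoff spans

sb_new <- function() {
  env <- new.env(parent = emptyenv())
  env$parts <- character()
  env$len <- 0L
  env$entities <- list()
  env$tes <- list()
  env$sections <- list()
  env
}

sb_add <- function(sb, s) {
  sb$parts[[length(sb$parts) + 1L]] <- s
  sb$len <- sb$len + nchar(s)
  invisible(sb)
}

sb_add_entity <- function(sb, surface) {
  id <- sprintf("me%d", length(sb$entities) + 1L)
  sb$entities[[length(sb$entities) + 1L]] <-
    list(me_id = id, start = sb$len, end = sb$len + nchar(surface))
  sb_add(sb, surface)
  id
}

sb_add_te <- function(sb, surface, value, kind = "other") {
  id <- sprintf("te%d", length(sb$tes) + 1L)
  sb$tes[[length(sb$tes) + 1L]] <-
    list(te_id = id, start = sb$len, end = sb$len + nchar(surface),
         value = value, kind = kind)
  sb_add(sb, surface)
  id
}

sb_begin_section <- function(sb, name) {
  sb$sections[[length(sb$sections) + 1L]] <- list(name = name, start = sb$len)
  invisible(sb)
}

sb_end_section <- function(sb) {
  k <- length(sb$sections)
  sb$sections[[k]]$end <- sb$len
  invisible(sb)
}

date_surface <- function(date, style) {
  switch(style,
    ymd_cn = sprintf("%d年%d月%d日", as.integer(format(date, "%Y")),
                     as.integer(format(date, "%m")), as.integer(format(date, "%d"))),
    md_cn = sprintf("%d月%d日", as.integer(format(date, "%m")),
                    as.integer(format(date, "%d"))),
    iso = format(date, "%Y-%m-%d")
  )
}

join_cn <- function(xs) paste(xs, collapse = "、")

# ---------------------------------------------------------------------------

#' Generate a corpus of synthetic clinical notes
#'
#' Seeded, fully deterministic generator of section-structured notes with
#' planted medical entities, temporal expressions and gold timeline indices.
#' Every note passes [validate_note()]; at `label_noise = 0` every gold index
#' is reachable from the entity's candidate-time set, so candidate coverage
#' is exactly 1. A manifest recording the planted template, mechanism and
#' relation of every entity is attached as `attr(corpus, "manifest")`, so
#' oracle checks never need to re-parse text.
#'
#' @param n_notes Number of notes to generate.
#' @param config A [generator_config()].
#' @param seed Optional integer; when supplied the generator runs under its
#'   own RNG state and restores the caller's afterwards.
#' @return An `mt_corpus` with a `manifest` attribute (tibble with one row per
#'   entity: `note_id`, `me_id`, `section`, `mechanism`, `te_id`, `relation`,
#'   `template`, `gold_index`, `noised`).
#' @export
generate_corpus <- function(n_notes, config = generator_config(), seed = NULL) {
  stopifnot(n_notes >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  notes <- vector("list", n_notes)
  manifests <- vector("list", n_notes)
  for (i in seq_len(n_notes)) {
    g <- generate_note(sprintf("note%04d", i), config)
    notes[[i]] <- g$note
    manifests[[i]] <- g$manifest
  }
  corpus <- new_corpus(notes)
  attr(corpus, "manifest") <- dplyr::bind_rows(manifests)
  corpus
}

generate_note <- function(note_id, config) {
  ents_pool <- entity_vocabulary()
  procs <- procedure_vocabulary()

  adm_date <- as.Date("2011-01-01") + sample.int(1095, 1) - 1L
  dis_date <- adm_date + sample(7:20, 1)
  n_hist <- min(max(rpois(1, max(config$mean_tes - 2, 1) * 0.6), 1L), 6L)
  n_stay <- min(max(rpois(1, max(config$mean_tes - 2, 1) * 0.4), 1L), 5L)
  hist_dates <- sort(adm_date - sample(1:400, n_hist))
  stay_span <- as.integer(dis_date - adm_date) - 1L
  n_stay <- min(n_stay, stay_span)
  stay_dates <- sort(adm_date + sample.int(stay_span, n_stay))

  optional <- stats::runif(3) < config$optional_section_prob
  plan <- list(
    list(name = "Chief complaint", n = 1L + rbinom(1, 1, 0.3)),
    list(name = "History of present illness", n = NA),   # TE section
    list(name = "Past medical history", n = 1L + rbinom(1, 2, 0.5)),
    if (optional[1]) list(name = "Personal history", n = 1L),
    list(name = "Physical examination", n = 1L + rbinom(1, 2, 0.5)),
    if (optional[2]) list(name = "Assistant examination", n = 1L + rbinom(1, 1, 0.5)),
    if (optional[3]) list(name = "Preliminary diagnosis", n = 1L),
    list(name = "Diagnosis and treatment", n = NA),      # TE section
    list(name = "Conditions in discharge", n = 1L + rbinom(1, 1, 0.7)),
    list(name = "Discharge orders", n = 1L)
  )
  plan <- plan[!vapply(plan, is.null, logical(1))]
  anchor_names <- vapply(plan, `[[`, character(1), "name")
  anchor_counts <- vapply(plan, function(p) {
    if (is.na(p$n)) 0L else as.integer(p$n)
  }, integer(1))
  at <- section_anchor_table()
  rel_of <- stats::setNames(at$anchor_relation, at$name)
  anchor_nodes <- sum(anchor_counts[rel_of[anchor_names] == "Simultaneous"])
  anchor_total <- sum(anchor_counts)

  n_te_sent <- n_hist + n_stay
  te_total <- max(n_te_sent, rpois(1, max(config$mean_entities - anchor_total, n_te_sent)))
  total <- anchor_total + te_total

  # node/interval plan: anchors' kind is fixed by their section; the in-text
  # templates absorb whatever the target mix still needs
  p_node_te <- (config$node_mix * total - anchor_nodes) / te_total
  p_node_te <- min(max(p_node_te, 0), 1)
  k_int <- rbinom(1, te_total, 1 - p_node_te)

  # entity allocation over TE sentences (each gets at least one, at most
  # three while room remains, to keep sentences clinically terse)
  alloc <- rep(1L, n_te_sent)
  extra <- te_total - n_te_sent
  for (e in seq_len(max(extra, 0L))) {
    open <- which(alloc < 3L)
    if (length(open) == 0) open <- seq_len(n_te_sent)
    a <- if (length(open) == 1) open else sample(open, 1)
    alloc[a] <- alloc[a] + 1L
  }
  hpi_alloc <- alloc[seq_len(n_hist)]
  stay_alloc <- alloc[n_hist + seq_len(n_stay)]

  # interval entities: BEFORE only in the earliest-history sentence, AFTER
  # only in the latest-history / latest-stay sentences, so gold intervals stay
  # derivable from in-sentence patterns alone
  rem <- k_int
  a_last_stay <- min(rem, stay_alloc[n_stay])
  rem <- rem - a_last_stay
  a_last_hist <- if (n_hist >= 2) min(rem, hpi_alloc[n_hist]) else 0L
  rem <- rem - a_last_hist
  n_B <- 0L
  if (n_hist >= 2 && rem > 0) {
    if (rem < hpi_alloc[1]) {
      # shrink the BEFORE sentence to the remaining interval quota and move
      # the surplus entities into a SIMULTANEOUS sentence
      surplus <- hpi_alloc[1] - rem
      hpi_alloc[1] <- rem
      mid <- if (n_hist >= 3) 2L else n_hist
      hpi_alloc[mid] <- hpi_alloc[mid] + surplus
    }
    n_B <- hpi_alloc[1]
  }

  sb <- sb_new()
  manifest <- list()
  plant <- function(me_id, section, mechanism, te_id, relation, template) {
    manifest[[length(manifest) + 1L]] <<- tibble(
      note_id = note_id, me_id = me_id, section = section,
      mechanism = mechanism, te_id = te_id, relation = relation,
      template = template)
  }
  draw_ents <- function(k) sample(ents_pool, k, replace = TRUE)

  # --- intro ("Other" section) with the admission time ---------------------
  sb_begin_section(sb, "Other")
  sb_add(sb, "患者于")
  adm_te <- sb_add_te(sb, date_surface(adm_date, "ymd_cn"),
                      format(adm_date, "%Y-%m-%d"), kind = "admission")
  sb_add(sb, "入院。\n")
  sb_end_section(sb)

  dis_te <- NULL

  anchor_sentence <- function(section, surfaces) {
    switch(section,
      "Chief complaint" = paste0(join_cn(surfaces), "数天。"),
      "Past medical history" = paste0("既往有", join_cn(surfaces), "病史。"),
      "Personal history" = paste0("否认", join_cn(surfaces), "等病史。"),
      "Physical examination" = paste0("查体见", join_cn(surfaces), "。"),
      "Assistant examination" = paste0("辅助检查示", join_cn(surfaces), "。"),
      "Preliminary diagnosis" = paste0("初步诊断为", join_cn(surfaces), "。"),
      "Conditions in discharge" = paste0("出院时", join_cn(surfaces), "明显好转。"),
      "Discharge orders" = paste0("出院后注意预防", join_cn(surfaces), "。")
    )
  }

  emit_anchor_section <- function(name, k) {
    hdr <- names(which(default_header_lexicon() == name))[1]
    sb_begin_section(sb, name)
    sb_add(sb, paste0(hdr, "："))
    if (name == "Conditions in discharge") {
      sb_add(sb, "患者于")
      dis_te <<- sb_add_te(sb, date_surface(dis_date, "ymd_cn"),
                           format(dis_date, "%Y-%m-%d"), kind = "discharge")
      sb_add(sb, "出院。")
    }
    surfaces <- draw_ents(k)
    tmpl <- anchor_sentence(name, surfaces)
    # write template around entity spans: split on the surfaces in order
    pieces <- strsplit(tmpl, paste(surfaces, collapse = "|"))[[1]]
    # safer explicit walk: rebuild with sb_add_entity at the right offsets
    rest <- tmpl
    for (s in surfaces) {
      at_pos <- regexpr(s, rest, fixed = TRUE)[1]
      sb_add(sb, substr(rest, 1, at_pos - 1))
      id <- sb_add_entity(sb, s)
      rel <- rel_of[[name]]
      rel_label <- c(Before = "BEFORE", Simultaneous = "SIMULTANEOUS",
                     After = "AFTER")[[rel]]
      anchor_id <- if (at$anchor[match(name, at$name)] == "discharge") dis_te else adm_te
      plant(id, name, "anchor", anchor_id, rel_label, paste0("anchor_", rel))
      rest <- substr(rest, at_pos + nchar(s), nchar(rest))
    }
    sb_add(sb, rest)
    sb_add(sb, "\n")
    sb_end_section(sb)
  }

  # TE sentence writers ------------------------------------------------------
  draw_style <- function() {
    sample(c("md_cn", "iso", "ymd_cn"), 1, prob = c(0.5, 0.3, 0.2))
  }
  emit_s_sentence <- function(date, surfaces, verb = "出现") {
    sb_add(sb, "于")
    te <- sb_add_te(sb, date_surface(date, draw_style()),
                    format(date, "%Y-%m-%d"))
    sb_add(sb, verb)
    ids <- character(0)
    for (j in seq_along(surfaces)) {
      if (j > 1) sb_add(sb, "、")
      ids <- c(ids, sb_add_entity(sb, surfaces[j]))
    }
    sb_add(sb, "。")
    list(te = te, ids = ids)
  }
  emit_b_sentence <- function(date, surfaces) {
    ids <- character(0)
    for (j in seq_along(surfaces)) {
      if (j > 1) sb_add(sb, "、")
      ids <- c(ids, sb_add_entity(sb, surfaces[j]))
    }
    sb_add(sb, "出现于")
    te <- sb_add_te(sb, date_surface(date, draw_style()),
                    format(date, "%Y-%m-%d"))
    sb_add(sb, "之前。")
    list(te = te, ids = ids)
  }
  emit_sa_sentence <- function(date, s_surfaces, a_surfaces) {
    sb_add(sb, "于")
    te <- sb_add_te(sb, date_surface(date, draw_style()),
                    format(date, "%Y-%m-%d"))
    sb_add(sb, "行")
    s_ids <- character(0)
    if (length(s_surfaces) == 0) {
      sb_add(sb, sample(procs, 1))
    } else {
      for (j in seq_along(s_surfaces)) {
        if (j > 1) sb_add(sb, "、")
        s_ids <- c(s_ids, sb_add_entity(sb, s_surfaces[j]))
      }
    }
    sb_add(sb, "，术后出现")
    a_ids <- character(0)
    for (j in seq_along(a_surfaces)) {
      if (j > 1) sb_add(sb, "、")
      a_ids <- c(a_ids, sb_add_entity(sb, a_surfaces[j]))
    }
    sb_add(sb, "。")
    list(te = te, s_ids = s_ids, a_ids = a_ids)
  }

  emit_te_section <- function(name, dates, alloc, n_B_here, a_last) {
    hdr <- names(which(default_header_lexicon() == name))[1]
    sb_begin_section(sb, name)
    sb_add(sb, paste0(hdr, "："))
    n_sent <- length(dates)
    for (s in seq_len(n_sent)) {
      k <- alloc[s]
      is_first <- s == 1L
      is_last <- s == n_sent
      if (is_first && n_B_here > 0) {
        out <- emit_b_sentence(dates[s], draw_ents(k))
        for (id in out$ids) plant(id, name, "te", out$te, "BEFORE", "b_sentence")
      } else if (is_last && a_last > 0) {
        n_s <- k - a_last
        out <- emit_sa_sentence(dates[s], draw_ents(max(n_s, 0)), draw_ents(a_last))
        for (id in out$s_ids) plant(id, name, "te", out$te, "SIMULTANEOUS", "sa_sentence")
        for (id in out$a_ids) plant(id, name, "te", out$te, "AFTER", "sa_sentence")
      } else {
        verb <- if (name == "Diagnosis and treatment") "予" else "出现"
        out <- emit_s_sentence(dates[s], draw_ents(k), verb)
        for (id in out$ids) plant(id, name, "te", out$te, "SIMULTANEOUS", "s_sentence")
      }
    }
    sb_add(sb, "\n")
    sb_end_section(sb)
  }

  for (p in plan) {
    if (p$name == "History of present illness") {
      emit_te_section(p$name, hist_dates, hpi_alloc, n_B, a_last_hist)
    } else if (p$name == "Diagnosis and treatment") {
      emit_te_section(p$name, stay_dates, stay_alloc, 0L, a_last_stay)
    } else {
      emit_anchor_section(p$name, p$n)
    }
  }

  text <- paste(sb$parts, collapse = "")
  sections <- dplyr::bind_rows(lapply(sb$sections, as_tibble))
  entities <- dplyr::bind_rows(lapply(sb$entities, as_tibble))
  tes <- dplyr::bind_rows(lapply(sb$tes, as_tibble))
  manifest <- dplyr::bind_rows(manifest)

  note <- clinical_note(note_id, text, sections, entities, tes,
                        admission_te = adm_te, discharge_te = dis_te,
                        validate = FALSE)
  tl <- build_timeline(note)
  gold <- vapply(seq_len(nrow(manifest)), function(i) {
    relation_to_index(manifest$te_id[i], manifest$relation[i], tl)
  }, integer(1))
  manifest$gold_index <- gold

  # optional planted noise: move the gold index outside the reachable set
  manifest$noised <- FALSE
  if (config$label_noise > 0) {
    for (i in seq_len(nrow(manifest))) {
      if (stats::runif(1) >= config$label_noise) next
      me <- note$entities[note$entities$me_id == manifest$me_id[i], ]
      sec_i <- section_of_span(note, me$start, me$end)
      sec <- note$sections[sec_i, ]
      cand <- unique(c(
        tryCatch(section_anchor_te(sec, note), error = function(e) character(0)),
        note$temporal_expressions$te_id[
          note$temporal_expressions$start >= sec$start &
            note$temporal_expressions$end <= sec$end]
      ))
      reach <- unique(unlist(lapply(cand, function(te) {
        n <- te_node_id(tl, te); c(n - 1L, n, n + 1L)
      })))
      pool <- setdiff(timeline_ids(tl), reach)
      if (length(pool) > 0) {
        manifest$gold_index[i] <- if (length(pool) == 1) pool else sample(pool, 1)
        manifest$noised[i] <- TRUE
      }
    }
  }

  note$entities$gold_index <-
    manifest$gold_index[match(note$entities$me_id, manifest$me_id)]
  validate_note(note)
  list(note = note, manifest = manifest)
}
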