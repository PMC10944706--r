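# small in-code fixtures shared across test files

make_scats <- function(scat_id, predator, date, x = 0, y = 0, area = "NE",
                       pack_id = NA_character_) {
  n <- length(scat_id)
  data.frame(scat_id = scat_id, predator = rep_len(predator, n),
             date = as.Date(rep_len(date, n)), x_m = rep_len(x, n),
             y_m = rep_len(y, n), area = rep_len(area, n),
             pack_id = rep_len(pack_id, n),
             year = as.integer(format(as.Date(rep_len(date, n)), "%Y")),
             stringsAsFactors = FALSE)
}

make_items <- function(scat_id, prey_species) {
  data.frame(scat_id = scat_id, prey_species = prey_species,
             stringsAsFactors = FALSE)
}

toy_traits <- function() {
  data.frame(
    species = c("kudu", "impala", "duiker", "steenbok", "buffalo",
                "scrub_hare"),
    mean_female_mass_kg = c(157, 40, 17, 11, 520, 2),
    water_dependency = c("medium", "high", "low", "low", "high", "low"),
    feeding_guild = c("browser", "mixed_feeder", "browser", "browser",
                      "grassland_grazer", "browser"),
    size_class = c("L", "M", "S", "S", "XL", "XS"),
    stringsAsFactors = FALSE)
}

write_scat_csv <- function(df, path) {
  df$pack_id[is.na(df$pack_id)] <- ""
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# long-format scat CSV rows (one per prey item)
scat_csv_row <- function(scat_id, predator, date, x, y, area, pack_id,
                         prey_species) {
  data.frame(scat_id = scat_id, predator = predator, date = date,
             x_m = x, y_m = y, area = area, pack_id = pack_id,
             prey_species = prey_species, stringsAsFactors = FALSE)
}
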