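# Shared settings for the numbered analysis scripts. Every script
# regenerates what it needs from this seed, so each can be run alone;
# artefact tables land under results/.

library(emsloc)

MASTER_SEED <- 20260925L
RESULTS_DIR <- file.path("results")
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

# Demo-scale city (200 areas / 12 stations x 2 slots); the study-scale
# profile is default_config(profile = "study").
CITY_CFG <- default_config(seed = MASTER_SEED)$synthetic_city

build_city <- function() generate_city(CITY_CFG, seed = MASTER_SEED)

build_od <- function(city) {
  od_matrix(city$graph,
            city$areas$table[, c("centroid_x", "centroid_y")],
            city$sites[, c("x", "y")],
            origin_ids = city$areas$table$area_id,
            destination_ids = city$sites$site_id)
}
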