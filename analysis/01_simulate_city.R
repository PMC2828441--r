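#!/usr/bin/env Rscript
# Build the synthetic city the rest of the analysis runs on: a jittered
# road lattice, Voronoi census small areas with demographics, candidate
# ambulance stations, and EMS case counts generated from the published
# demand model with noise calibrated so a refit attains R^2 ~ 0.71.

source(file.path("analysis", "_common.R"))

city <- build_city()

write_road_graph_csv(city$graph,
                     file.path(RESULTS_DIR, "city_nodes.csv"),
                     file.path(RESULTS_DIR, "city_edges.csv"))
write_areas_geojson(city$areas, file.path(RESULTS_DIR, "city_areas.geojson"))
utils::write.csv(city$areas$table, file.path(RESULTS_DIR, "city_areas.csv"),
                 row.names = FALSE)
utils::write.csv(city$sites, file.path(RESULTS_DIR, "city_sites.csv"),
                 row.names = FALSE)
utils::write.csv(city$cases, file.path(RESULTS_DIR, "city_case_points.csv"),
                 row.names = FALSE)

tab <- city$areas$table
cat(sprintf("city: %d census areas, %d road nodes, %d stations (%d slots)\n",
            nrow(tab), nrow(city$graph$nodes), nrow(city$sites),
            sum(city$sites$max_slots)))
cat(sprintf("population %d (mean %.0f per area), companies %d\n",
            sum(tab$pop_total), mean(tab$pop_total),
            sum(tab$companies_5plus)))
cat(sprintf("case counts: total %d, calibrated noise sd %.2f cases\n",
            sum(tab$observed_cases), city$noise_sd))

# Round trip: scattering the cases and recounting by point-in-polygon
# must reproduce the per-area counts exactly.
recount <- count_points_in_polygons(city$cases, city$areas)
stopifnot(identical(as.integer(recount), tab$observed_cases))
cat("point-in-polygon recount reproduces the generated counts exactly\n")
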