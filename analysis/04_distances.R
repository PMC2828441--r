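#!/usr/bin/env Rscript
# Build the origin-destination matrix of shortest-path road distances
# between every census-area envelope centroid and every candidate
# station, and convert headline distances to travel times at 30 km/h.

source(file.path("analysis", "_common.R"))

city <- build_city()
od <- build_od(city)
write_od_csv(od, long_path = file.path(RESULTS_DIR, "od_long.csv"),
             dense_path = file.path(RESULTS_DIR, "od_dense.csv"))

cat(sprintf("OD matrix: %d areas x %d stations\n", nrow(od), ncol(od)))
cat(sprintf("distance range %.0f-%.0f m; median snap error %.0f m\n",
            min(od), max(od), stats::median(attr(od, "origin_snap_m"))))
w <- city$areas$table$observed_cases
dmin <- apply(od, 1, min)
cat(sprintf("case-weighted nearest-station distance %.0f m = %.0f s at 30 km/h\n",
            sum(w * dmin) / sum(w),
            distance_to_time(sum(w * dmin) / sum(w), 30)))
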