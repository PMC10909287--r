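#!/usr/bin/env Rscript
# Travel times to the closest ED: split road segments at intersections,
# drop walking roads, build the minute-weighted graph, fuse the grids, snap
# every fused-cell centroid to its nearest junction and route.

library(dynaccess)

sc <- scenario_config()
static <- generate_static_grid(sc)
classes <- assign_urban_classes(static, sc)
eds <- generate_eds(static, sc)
roads <- generate_road_network(sc)
dyn <- generate_dynamic_observations(static, sc)

split <- split_segments_at_intersections(roads)
message(sprintf("splitting: %d segments -> %d", nrow(roads), nrow(split)))
kept <- filter_walking_roads(split)
message(sprintf("walking roads removed: %d", nrow(split) - nrow(kept)))
graph <- build_graph(kept)

fused <- attach_urban_class(fuse_grids(static, dyn$cells), classes)
snap <- snap_cells(fused, graph, max_dist_m = 5000)
assignments <- closest_facility(graph, eds, snap)
message(sprintf("%d of %d cells unreachable and omitted (%.1f%%)",
                sum(!assignments$reachable), nrow(fused),
                100 * mean(!assignments$reachable)))

write.csv(assignments, "scratch/analysis/assignments.csv", row.names = FALSE)
reach <- assignments[assignments$reachable, ]
cat(sprintf("travel time to closest ED (min): median %.1f, p90 %.1f, max %.1f\n",
            median(reach$travel_time_min),
            quantile(reach$travel_time_min, 0.9), max(reach$travel_time_min)))
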