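#' stovermorph: multi-scale morphometrics of pretreated biomass micrographs
#'
#' Quantitative image analysis of dilute-acid pretreated lignocellulosic
#' biomass at four imaging scales, plus ground-truthed synthetic generators
#' and a structure-vs-digestibility correlation report.  The typical flow:
#'
#' * particle fields (flatbed scans): [segment_particles()],
#'   [compute_descriptors()], [particle_histograms()], [particle_summary()];
#' * confocal wall sections: [threshold_mask()] / [otsu_threshold()],
#'   [distance_map()], [medial_axis()], [sample_thickness()],
#'   [summarize_thickness()];
#' * SEM surfaces: [roughness_of_roi()], [roughness_summary()];
#' * TEM wall sections: [compute_void_threshold()], [quantify_void()],
#'   [void_shape_descriptors()];
#' * reporting: [build_correlation_table()], [render_report()], with the
#'   bundled [reactor_morphometrics()] dataset as worked example;
#' * synthetic benchmarks: [make_particle_field()], [make_cell_lattice()],
#'   [make_textured_surface()], [make_tem_wall()].
#'
#' @keywords internal
#' @importFrom stats rnorm runif rlnorm sd var
#' @importFrom utils read.csv write.csv
"_PACKAGE"
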