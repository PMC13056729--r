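# Pin BLAS to one thread: the container exposes a single CPU, and OpenBLAS's
# core autodetection otherwise spawns a contending thread pool that slows the
# dense kernels several-fold. Must run before the first BLAS call.
Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1")
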