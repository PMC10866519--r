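# Build with the system toolchain: the conda cross-compiler's sysroot targets
# a newer glibc than the runtime loader provides, so its objects fail to load.
override CXX = g++ $(CXX17STD)
override CXX17 = g++
override CC = gcc
PKG_CXXFLAGS = -O3
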