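# Hot loops in the engine need post-SSE2 vector math (nearbyintf etc.);
# append tuning flags after the site-wide CXXFLAGS so they take effect.
ENGINE_FLAGS = -O3 -march=native -fno-math-errno -funsafe-math-optimizations -fno-trapping-math -mprefer-vector-width=512 -mrecip=div

all: $(SHLIB)

engine.o: engine.cpp
	$(CXX) $(ALL_CPPFLAGS) $(ALL_CXXFLAGS) $(ENGINE_FLAGS) -c engine.cpp -o engine.o

.PHONY: all
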