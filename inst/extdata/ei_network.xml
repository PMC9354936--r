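<!--
  Two conductance-LIF populations in an E-I configuration.

  Before running, generate the grid support files referenced below, e.g.

    popgrid generate - -model cond3d - -name cond3d - -dir .      (no spaces in
    the real flags; XML comments cannot contain double hyphens)

  or in R:  generate_nd_grid(cond3d_derivative, "cond3d",
                             c(-0.2, -0.2, -80), c(5.4, 5.4, 40),
                             c(50, 50, 50), -50.4, -70.6)

  Dimension indices are 0-based into the state vector [u, w, v] (membrane
  potential last): excitatory jumps act on dimension 1 (the excitatory
  conductance w), inhibitory jumps on dimension 0 (the inhibitory
  conductance u). Published examples of this dialect label the inhibitory
  dimension "2"; under the [u, w, v] state order used here, u is dimension
  0. The external drives carry an explicit rate attribute (500 Hz) and a
  1.5 nS/cm^2 efficacy; the same configuration is sometimes printed with
  efficacy 0.15, but the prose value 1.5 is used here.
-->
<Simulation>
<WeightType>CustomConnectionParameters</WeightType>
<Algorithms>
<Algorithm type="GridAlgorithmGroup" name="COND3D" modelfile="cond3d.model" tau_refractive="0.002" transformfile="cond3d.tmat" start_v="-65" start_w="0.00001" start_u="0.00001">
<TimeStep>1e-03</TimeStep>
</Algorithm>
</Algorithms>
<Nodes>
<Node algorithm="COND3D" name="E" type="EXCITATORY" />
<Node algorithm="COND3D" name="I" type="INHIBITORY" />
</Nodes>
<Connections>
<IncomingConnection Node="E" num_connections="1" efficacy="1.5" delay="0.0" dimension="1" rate="500" />
<IncomingConnection Node="I" num_connections="1" efficacy="1.5" delay="0.0" dimension="1" rate="500" />
<Connection In="E" Out="E" num_connections="50" efficacy="1" delay="0.003" dimension="1" />
<Connection In="I" Out="E" num_connections="50" efficacy="4" delay="0.003" dimension="0" />
<Connection In="E" Out="I" num_connections="50" efficacy="1" delay="0.003" dimension="1" />
<Connection In="I" Out="I" num_connections="50" efficacy="4" delay="0.003" dimension="0" />
</Connections>
<Reporting>
<Display node="E" />
<Average node="E" t_interval="0.001" />
<Average node="I" t_interval="0.001" />
<Rate node="E" t_interval="0.001" />
<Rate node="I" t_interval="0.001" />
</Reporting>
<SimulationRunParameter>
<master_steps>10</master_steps>
<t_end>1.0</t_end>
<t_step>1e-03</t_step>
<name_log>cond.log</name_log>
</SimulationRunParameter>
</Simulation>
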