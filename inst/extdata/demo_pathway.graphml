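<?xml version="1.0" encoding="UTF-8"?>
<graphml xmlns="http://graphml.graphdrawing.org/xmlns"
         xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance"
         xsi:schemaLocation="http://graphml.graphdrawing.org/xmlns
         http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd">
<!-- Created by igraph -->
  <key id="v_name" for="node" attr.name="name" attr.type="string"/>
  <key id="v_label" for="node" attr.name="label" attr.type="string"/>
  <key id="v_localization" for="node" attr.name="localization" attr.type="string"/>
  <graph id="G" edgedefault="undirected">
    <node id="n0">
      <data key="v_name">n01</data>
      <data key="v_label">n01</data>
      <data key="v_localization">cytoplasm</data>
    </node>
    <node id="n1">
      <data key="v_name">n02</data>
      <data key="v_label">n02</data>
      <data key="v_localization">cytoplasm</data>
    </node>
    <node id="n2">
      <data key="v_name">n03</data>
      <data key="v_label">n03</data>
      <data key="v_localization">plasma_membrane</data>
    </node>
    <node id="n3">
      <data key="v_name">n04</data>
      <data key="v_label">n04</data>
      <data key="v_localization">cytoplasm</data>
    </node>
    <node id="n4">
      <data key="v_name">n05</data>
      <data key="v_label">n05</data>
      <data key="v_localization">cytoplasm</data>
    </node>
    <node id="n5">
      <data key="v_name">n06</data>
      <data key="v_label">n06</data>
      <data key="v_localization">mitochondria</data>
    </node>
    <node id="n6">
      <data key="v_name">n07</data>
      <data key="v_label">n07</data>
      <data key="v_localization">cytoplasm</data>
    </node>
    <node id="n7">
      <data key="v_name">n08</data>
      <data key="v_label">n08</data>
      <data key="v_localization">cytoplasm</data>
    </node>
    <node id="n8">
      <data key="v_name">n09</data>
      <data key="v_label">n09</data>
      <data key="v_localization">cytoplasm</data>
    </node>
    <node id="n9">
      <data key="v_name">n10</data>
      <data key="v_label">n10</data>
      <data key="v_localization">cytoplasm</data>
    </node>
    <node id="n10">
      <data key="v_name">n11</data>
      <data key="v_label">n11</data>
      <data key="v_localization">mitochondria</data>
    </node>
    <node id="n11">
      <data key="v_name">n12</data>
      <data key="v_label">n12</data>
      <data key="v_localization">cytoplasm</data>
    </node>
    <node id="n12">
      <data key="v_name">n13</data>
      <data key="v_label">n13</data>
      <data key="v_localization">nucleus</data>
    </node>
    <node id="n13">
      <data key="v_name">n14</data>
      <data key="v_label">n14</data>
      <data key="v_localization">cytoplasm</data>
    </node>
    <node id="n14">
      <data key="v_name">n15</data>
      <data key="v_label">n15</data>
      <data key="v_localization">extracellular</data>
    </node>
    <node id="n15">
      <data key="v_name">n16</data>
      <data key="v_label">n16</data>
      <data key="v_localization">nucleus</data>
    </node>
    <node id="n16">
      <data key="v_name">n17</data>
      <data key="v_label">n17</data>
      <data key="v_localization">extracellular</data>
    </node>
    <node id="n17">
      <data key="v_name">n18</data>
      <data key="v_label">n18</data>
      <data key="v_localization">mitochondria</data>
    </node>
    <node id="n18">
      <data key="v_name">n19</data>
      <data key="v_label">n19</data>
      <data key="v_localization">nucleus</data>
    </node>
    <node id="n19">
      <data key="v_name">n20</data>
      <data key="v_label">n20</data>
      <data key="v_localization">plasma_membrane</data>
    </node>
    <node id="n20">
      <data key="v_name">n21</data>
      <data key="v_label">n21</data>
      <data key="v_localization">plasma_membrane</data>
    </node>
    <node id="n21">
      <data key="v_name">n22</data>
      <data key="v_label">n22</data>
      <data key="v_localization">cytoplasm</data>
    </node>
    <node id="n22">
      <data key="v_name">n23</data>
      <data key="v_label">n23</data>
      <data key="v_localization">extracellular</data>
    </node>
    <node id="n23">
      <data key="v_name">n24</data>
      <data key="v_label">n24</data>
      <data key="v_localization">cytoplasm</data>
    </node>
    <edge source="n0" target="n1">
    </edge>
    <edge source="n0" target="n2">
    </edge>
    <edge source="n0" target="n3">
    </edge>
    <edge source="n0" target="n4">
    </edge>
    <edge source="n0" target="n6">
    </edge>
    <edge source="n0" target="n11">
    </edge>
    <edge source="n0" target="n15">
    </edge>
    <edge source="n0" target="n18">
    </edge>
    <edge source="n0" target="n20">
    </edge>
    <edge source="n1" target="n4">
    </edge>
    <edge source="n2" target="n11">
    </edge>
    <edge source="n2" target="n12">
    </edge>
    <edge source="n2" target="n15">
    </edge>
    <edge source="n2" target="n17">
    </edge>
    <edge source="n3" target="n5">
    </edge>
    <edge source="n3" target="n7">
    </edge>
    <edge source="n3" target="n9">
    </edge>
    <edge source="n3" target="n13">
    </edge>
    <edge source="n4" target="n11">
    </edge>
    <edge source="n4" target="n14">
    </edge>
    <edge source="n4" target="n16">
    </edge>
    <edge source="n4" target="n19">
    </edge>
    <edge source="n4" target="n21">
    </edge>
    <edge source="n4" target="n22">
    </edge>
    <edge source="n4" target="n23">
    </edge>
    <edge source="n5" target="n10">
    </edge>
    <edge source="n7" target="n8">
    </edge>
    <edge source="n17" target="n21">
    </edge>
  </graph>
</graphml>
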